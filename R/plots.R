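#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   facet_grid facet_wrap labs scale_fill_gradient theme_minimal
#' @export
ggplot2::autoplot

#' Heatmap of a pathway-based score matrix
#'
#' @param object A `score_matrix`.
#' @param ... Unused.
#' @return A ggplot object: samples x samples tile plot, darker = more
#'   pathways separating the pair.
#' @export
autoplot.score_matrix <- function(object, ...) {
  m <- unclass_keep_dim(object)
  df <- tidyr::expand_grid(sample1 = rownames(m), sample2 = colnames(m))
  df$score <- as.vector(t(m))
  ggplot(df, aes(x = factor(.data$sample1, rownames(m)),
                 y = factor(.data$sample2, rev(colnames(m))),
                 fill = .data$score)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, NA)) +
    labs(x = NULL, y = NULL, fill = "score",
         title = sprintf("Pathway-based distance score (%d voting pathways)",
                         attr(object, "n_voting_pathways"))) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Connectivity trace of a k selection
#'
#' @param object A `k_selection`.
#' @param ... Unused.
#' @return A ggplot object: connectivity (to be minimized) against the
#'   candidate number of clusters, the selected k highlighted.
#' @export
autoplot.k_selection <- function(object, ...) {
  tr <- tidy(object)
  ggplot(tr, aes(x = .data$k, y = .data$connectivity)) +
    geom_line() +
    geom_point(aes(colour = .data$selected), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 guide = "none") +
    labs(x = "number of clusters", y = "connectivity (minimize)",
         title = sprintf("Selected k = %d (%s)", object$k, object$method)) +
    theme_minimal()
}

#' Benchmark summary plots
#'
#' @param object A `benchmark_report`.
#' @param metric `"success_rate"` (probability that the connectivity
#'   criterion selects the planted number of groups) or `"median_purity"`.
#' @param ... Unused.
#' @return A ggplot object faceted by clustering algorithm, one line per
#'   distance method against `delta`.
#' @export
autoplot.benchmark_report <- function(object, metric = c("success_rate", "median_purity"), ...) {
  metric <- match.arg(metric)
  s <- object$summary
  ggplot(s, aes(x = .data$delta, y = .data[[metric]],
                colour = .data$method, group = .data$method)) +
    geom_line() + geom_point() +
    facet_wrap(~clustering) +
    labs(x = expression(delta), y = metric, colour = "distance") +
    theme_minimal()
}
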