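#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-pathway clustering results into a long tibble
#'
#' @param x A `pathway_clusterings` list.
#' @param ... Unused.
#' @return A tibble with columns `pathway`, `sample_id`, `label`, `m_k`,
#'   `method` (one row per pathway x sample), the long export format.
#' @export
tidy.pathway_clusterings <- function(x, ...) {
  purrr::map_dfr(x, function(pc) {
    tibble::tibble(pathway = pc$pathway_name,
                   sample_id = names(pc$labels),
                   label = unname(pc$labels),
                   m_k = pc$m_k, method = pc$method)
  })
}

#' Per-pathway summary of a clustering run
#'
#' @param x A `pathway_clusterings` list.
#' @param ... Unused.
#' @return A tibble with one row per pathway: `pathway`, `m_k`,
#'   `n_genes_used`, `method`, `model`.
#' @export
glance.pathway_clusterings <- function(x, ...) {
  purrr::map_dfr(x, function(pc) {
    tibble::tibble(pathway = pc$pathway_name, m_k = pc$m_k,
                   n_genes_used = pc$n_genes_used, method = pc$method,
                   model = pc$model)
  })
}

#' Tidy a single pathway clustering
#'
#' @param x A `pathway_clustering`.
#' @param ... Unused.
#' @return A tibble with `sample_id` and `label`.
#' @export
tidy.pathway_clustering <- function(x, ...) {
  tibble::tibble(pathway = x$pathway_name, sample_id = names(x$labels),
                 label = unname(x$labels), m_k = x$m_k, method = x$method)
}

#' @export
glance.pathway_clustering <- function(x, ...) {
  tibble::tibble(pathway = x$pathway_name, m_k = x$m_k,
                 n_genes_used = x$n_genes_used, method = x$method,
                 model = x$model)
}

#' Tidy a score or distance matrix into sample pairs
#'
#' @param x A `score_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per unordered sample pair: `sample1`,
#'   `sample2`, `score`.
#' @export
tidy.score_matrix <- function(x, ...) {
  m <- unclass_keep_dim(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(sample1 = rownames(m)[idx[, 1L]],
                 sample2 = colnames(m)[idx[, 2L]],
                 score = m[idx])
}

#' @export
glance.score_matrix <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x),
                 n_voting_pathways = attr(x, "n_voting_pathways"),
                 mean_score = mean(unclass_keep_dim(x)[upper.tri(x)]))
}

#' Tidy a k-selection trace
#'
#' @param x A `k_selection` from [select_k_connectivity()].
#' @param ... Unused.
#' @return The per-k trace tibble (`k`, `connectivity`, `dunn`) with a
#'   `selected` flag.
#' @export
tidy.k_selection <- function(x, ...) {
  dplyr::mutate(x$trace, selected = .data$k == x$k)
}

#' @export
glance.k_selection <- function(x, ...) {
  tibble::tibble(method = x$method, k = x$k,
                 connectivity = x$trace$connectivity[x$trace$k == x$k],
                 dunn = x$trace$dunn[x$trace$k == x$k])
}

#' Tidy benchmark results
#'
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @return The per-replicate record tibble (without the nested traces).
#' @export
tidy.benchmark_report <- function(x, ...) {
  dplyr::select(x$records, -"trace")
}

#' @export
glance.benchmark_report <- function(x, ...) {
  x$summary
}

#' Tidy a simulator moment report
#'
#' @param x A `moment_report`.
#' @param ... Unused.
#' @return A long tibble of all checked moments: `moment` (variance, mean,
#'   correlation), `target`, `estimate`, `z`.
#' @export
tidy.moment_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$gene_variances, moment = "variance", id = .data$gene,
                     estimate = .data$variance, target = .data$target, z = .data$z),
    dplyr::transmute(x$group_means, moment = "mean",
                     id = paste0(.data$gene, ":g", .data$group),
                     estimate = .data$mean, target = .data$target, z = .data$z),
    if (nrow(x$pair_correlations)) {
      dplyr::transmute(x$pair_correlations, moment = "correlation",
                       id = paste0(.data$gene1, ":", .data$gene2),
                       estimate = .data$r, target = .data$target, z = .data$z)
    }
  )
}

#' @export
glance.moment_report <- function(x, ...) {
  tibble::tibble(
    n_chosen_genes = nrow(x$gene_variances),
    max_abs_z_variance = max(abs(x$gene_variances$z)),
    max_abs_z_mean = max(abs(x$group_means$z)),
    max_abs_z_correlation = if (nrow(x$pair_correlations))
      max(abs(x$pair_correlations$z)) else NA_real_
  )
}

#' @importFrom rlang .data
NULL
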