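#' Options for per-pathway Gaussian mixture clustering
#'
#' The number of mixture components is selected by BIC over `1:k_max`
#' candidates, with BIC oriented as `2*logLik - df*log(n)` (maximized).
#' `models` names the mclust covariance families searched; the default is
#' the spherical and diagonal set, which keeps the parameter count of a
#' k-component model linear in the pathway size so that BIC can still favour
#' multi-component fits at cohort-scale sample sizes (~120 subjects). The
#' unconstrained family (`"VVV"`, (p^2+3p)/2 parameters per component at
#' k = 1) can be requested explicitly but is rarely selectable once the
#' pathway has more than a handful of genes.
#'
#' @param k_max Largest candidate component count (default 5).
#' @param models Character vector of mclust model names to search.
#' @param seed Optional integer seed (the mixture fit itself is
#'   deterministic; the seed is consumed by operations layered on top,
#'   e.g. downsampling).
#' @return A list of class `gmm_options`.
#' @export
gmm_options <- function(k_max = 5L,
                        models = c("EII", "VII", "EEI", "VEI", "EVI", "VVI"),
                        seed = NULL) {
  assert_scalar_number(k_max, "k_max", min = 1)
  structure(list(k_max = as.integer(k_max), models = models, seed = seed),
            class = "gmm_options")
}

#' Cluster samples with a Gaussian mixture model, selecting k by BIC
#'
#' Fits mixtures with `1:k_max` components (via mclust, which initializes
#' EM from deterministic model-based hierarchical clustering) and keeps the
#' fit maximizing `BIC = 2*logLik - df*log(n)`, ties going to the smaller k.
#' Hard labels are maximum-posterior assignments, relabeled to consecutive
#' integers in order of first appearance; components left empty by the hard
#' assignment are dropped, so `m_k` always equals the number of distinct
#' labels. If every multi-component fit fails, the result degrades to a
#' single cluster rather than aborting — such pathways simply do not vote
#' in the distance score.
#'
#' @param data Numeric matrix, samples in rows, genes (features) in columns.
#' @param options A [gmm_options()] list.
#' @param pathway_name Optional name recorded in the result.
#' @return A list of class `pathway_clustering` with elements
#'   `pathway_name`, `labels` (named integer vector), `m_k`,
#'   `n_genes_used`, `method` (`"gmm"`), `model` (selected mclust family)
#'   and `bic_trace` (tibble with `k`, `model`, `bic` for the best model per
#'   k).
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
#' rownames(x) <- paste0("s", 1:60)
#' fit <- fit_gmm_select_k(x, gmm_options())
#' fit$m_k
fit_gmm_select_k <- function(data, options = gmm_options(), pathway_name = NA_character_) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (!all(is.finite(data))) abort("`data` contains non-finite values.")
  n <- nrow(data)
  if (n < 2L) abort("need at least 2 samples to cluster.")
  sample_ids <- rownames(data) %||% as.character(seq_len(n))

  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(data, G = seq_len(options$k_max),
                                    modelNames = options$models,
                                    verbose = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # total failure: fall back to the closed-form single-Gaussian "fit"
    labels <- rep(1L, n)
    names(labels) <- sample_ids
    return(new_pathway_clustering(pathway_name, labels, 1L, ncol(data),
                                  "gmm", NA_character_, empty_bic_trace()))
  }

  labels <- relabel_consecutive(as.integer(fit$classification))
  names(labels) <- sample_ids
  bic <- fit$BIC
  trace <- tibble::tibble(
    k = rep(as.integer(rownames(bic)), ncol(bic)),
    model = rep(colnames(bic), each = nrow(bic)),
    bic = as.vector(bic)
  )
  trace <- trace[!is.na(trace$bic), , drop = FALSE]
  best_per_k <- trace |>
    dplyr::group_by(.data$k) |>
    dplyr::slice_max(.data$bic, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()

  new_pathway_clustering(pathway_name, labels, max(labels), ncol(data),
                         "gmm", fit$modelName, best_per_k)
}

new_pathway_clustering <- function(pathway_name, labels, m_k, n_genes_used,
                                   method, model, bic_trace) {
  structure(
    list(pathway_name = pathway_name, labels = labels, m_k = as.integer(m_k),
         n_genes_used = as.integer(n_genes_used), method = method,
         model = model, bic_trace = bic_trace),
    class = "pathway_clustering"
  )
}

empty_bic_trace <- function() {
  tibble::tibble(k = integer(), model = character(), bic = double())
}

#' @export
print.pathway_clustering <- function(x, ...) {
  cat(sprintf("<pathway_clustering> %s: %d cluster(s) over %d samples (%s, %d genes)\n",
              x$pathway_name, x$m_k, length(x$labels), x$method, x$n_genes_used))
  invisible(x)
}

#' Parameter count of a k-component Gaussian mixture
#'
#' For the unconstrained (full-covariance) family the degrees of freedom are
#' `k - 1` mixing weights plus `k*p` means plus `k*p*(p+1)/2` covariance
#' entries; at `k = 1` this reduces to `(p^2 + 3p)/2`, the count that makes
#' large pathways unfittable at cohort sample sizes and motivates
#' downsampling.
#'
#' @param k Number of components.
#' @param p Number of features (genes).
#' @return Integer parameter count.
#' @export
gmm_full_df <- function(k, p) {
  as.integer(k - 1 + k * p + k * p * (p + 1) / 2)
}

#' Cluster all samples once per pathway
#'
#' Runs [fit_gmm_select_k()] on the samples-by-member-genes submatrix of
#' every pathway in the collection (which must already be matched to the
#' expression matrix, see [match_pathways()]). When `downsample` options are
#' supplied, pathways larger than the downsampling trigger are clustered via
#' [downsample_cluster_pathway()] instead. A per-pathway failure degrades to
#' a single-cluster result and never aborts the run. Per-pathway seeds are
#' derived deterministically from `seed` and the pathway index, so a full
#' run is reproducible and individual pathways can be re-run in isolation.
#'
#' @param expr Gene-by-sample numeric matrix.
#' @param sets Matched gene-set collection (every gene present in `expr`).
#' @param options A [gmm_options()] list.
#' @param downsample Optional [downsample_options()]; `NULL` disables
#'   downsampling.
#' @param seed Master seed for the run (defaults to `options$seed`).
#' @return A list of class `pathway_clusterings` (one `pathway_clustering`
#'   per pathway, in collection order). Use [tidy()] for a long tibble or
#'   [glance()] for the per-pathway summary.
#' @export
cluster_all_pathways <- function(expr, sets, options = gmm_options(),
                                 downsample = NULL, seed = NULL) {
  check_expression_matrix(expr)
  if (length(sets) == 0L) abort("empty gene-set collection; run match_pathways() first.")
  missing <- setdiff(unique(unlist(sets)), rownames(expr))
  if (length(missing)) {
    abort(sprintf("gene-set collection is not matched to `expr` (%d unmeasured gene(s), e.g. '%s').",
                  length(missing), missing[1L]))
  }
  seed <- seed %||% options$seed %||% 0L

  out <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    genes <- sets[[i]]
    sub <- t(expr[genes, , drop = FALSE])
    res <- tryCatch({
      if (!is.null(downsample) && length(genes) > downsample$trigger_size) {
        downsample_cluster_pathway(sub, opts = downsample, gmm = options,
                                   seed = derive_seed(seed, i),
                                   pathway_name = names(sets)[i])
      } else {
        fit_gmm_select_k(sub, options, pathway_name = names(sets)[i])
      }
    }, error = function(e) {
      warn(sprintf("pathway '%s' failed (%s); recorded as a single cluster.",
                   names(sets)[i], conditionMessage(e)))
      labels <- rep(1L, ncol(expr))
      names(labels) <- colnames(expr)
      new_pathway_clustering(names(sets)[i], labels, 1L, length(genes),
                             "gmm", NA_character_, empty_bic_trace())
    })
    out[[i]] <- res
  }
  structure(out, class = "pathway_clusterings", sample_ids = colnames(expr))
}

#' @export
print.pathway_clusterings <- function(x, ...) {
  mk <- vapply(x, `[[`, integer(1), "m_k")
  cat(sprintf("<pathway_clusterings> %d pathways over %d samples; %d with m_k > 1\n",
              length(x), length(attr(x, "sample_ids")), sum(mk > 1L)))
  invisible(x)
}
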