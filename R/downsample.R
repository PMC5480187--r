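#' Options for downsampling large pathways
#'
#' A k-component full-dimensional mixture over a large pathway has far more
#' parameters than a cohort has samples, so large pathways are broken into
#' many small random gene subsets: each subset is clustered on its own, the
#' subset votes are pooled into a within-pathway distance, and that distance
#' is clustered once to give the pathway's partition. 100 subsets of 10
#' genes is the default, sized for ~120-subject cohorts.
#'
#' @param subset_size Genes drawn per subset (default 10).
#' @param n_subsets Number of random subsets (default 100).
#' @param trigger_size Pathways with more matched genes than this are
#'   downsampled by [cluster_all_pathways()] (default 10).
#' @param k_range Candidate cluster counts for the final K-means on the vote
#'   matrix (default 2:5).
#' @param L Neighbor count for the connectivity criterion used to pick k.
#' @param kmeans_n_init K-means restarts.
#' @return A list of class `downsample_options`.
#' @export
downsample_options <- function(subset_size = 10L, n_subsets = 100L,
                               trigger_size = 10L, k_range = 2:5,
                               L = 10L, kmeans_n_init = 20L) {
  assert_scalar_number(subset_size, "subset_size", min = 2)
  assert_scalar_number(n_subsets, "n_subsets", min = 1)
  if (subset_size > trigger_size) {
    abort("`subset_size` must not exceed `trigger_size`.")
  }
  structure(list(subset_size = as.integer(subset_size),
                 n_subsets = as.integer(n_subsets),
                 trigger_size = as.integer(trigger_size),
                 k_range = as.integer(k_range),
                 L = as.integer(L),
                 kmeans_n_init = as.integer(kmeans_n_init)),
            class = "downsample_options")
}

#' Cluster one large pathway by downsampling gene subsets
#'
#' Draws `n_subsets` random subsets of `subset_size` member genes (without
#' replacement within a subset), clusters the samples with each subset via
#' [fit_gmm_select_k()], and forms the subset-vote distance: for a sample
#' pair, the proportion of subsets with more than one component that assign
#' the pair to different clusters (single-cluster subsets abstain, mirroring
#' the pathway-level filter). The vote matrix is then treated as a data
#' matrix (columns as feature vectors), k is chosen from `k_range` by
#' minimizing the connectivity criterion of K-means partitions, and the
#' K-means partition at that k becomes the pathway's single clustering
#' result. If no subset finds structure the pathway degrades to one cluster.
#'
#' @param expr_subset Numeric matrix, samples in rows, the pathway's matched
#'   genes in columns.
#' @param opts A [downsample_options()] list.
#' @param gmm A [gmm_options()] list for the per-subset fits.
#' @param seed Integer seed for subset draws and K-means.
#' @param pathway_name Optional name recorded in the result.
#' @return A `pathway_clustering` with `method = "downsampled"` (or
#'   `"gmm"` when the pathway is too small to downsample and falls back to
#'   a direct fit).
#' @export
downsample_cluster_pathway <- function(expr_subset, opts = downsample_options(),
                                       gmm = gmm_options(), seed = 0L,
                                       pathway_name = NA_character_) {
  if (!is.matrix(expr_subset)) expr_subset <- as.matrix(expr_subset)
  s_k <- ncol(expr_subset)
  n <- nrow(expr_subset)
  sample_ids <- rownames(expr_subset) %||% as.character(seq_len(n))
  if (s_k < opts$subset_size) {
    inform(sprintf("pathway '%s' has %d genes < subset_size %d; direct fit used.",
                   pathway_name, s_k, opts$subset_size))
    return(fit_gmm_select_k(expr_subset, gmm, pathway_name = pathway_name))
  }

  votes <- matrix(0, n, n)        # disagreement counts
  n_voting <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(opts$n_subsets)) {
      idx <- sample.int(s_k, opts$subset_size)
      fit <- fit_gmm_select_k(expr_subset[, idx, drop = FALSE], gmm)
      if (fit$m_k > 1L) {
        lab <- unname(fit$labels)
        votes <- votes + (outer(lab, lab, `!=`) * 1)
        n_voting <- n_voting + 1L
      }
    }
  })

  if (n_voting == 0L) {
    labels <- rep(1L, n); names(labels) <- sample_ids
    return(new_pathway_clustering(pathway_name, labels, 1L, s_k,
                                  "downsampled", NA_character_, empty_bic_trace()))
  }

  vote_dist <- votes / n_voting
  dimnames(vote_dist) <- list(sample_ids, sample_ids)
  sel <- select_k_connectivity(
    vote_dist, features = vote_dist, method = "kmeans",
    opts = eval_options(L = opts$L, k_range = opts$k_range,
                        kmeans_n_init = opts$kmeans_n_init,
                        seed = derive_seed(seed, 1L))
  )
  labels <- relabel_consecutive(sel$partition)
  names(labels) <- sample_ids
  new_pathway_clustering(pathway_name, labels, max(labels), s_k,
                         "downsampled", NA_character_, empty_bic_trace())
}
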