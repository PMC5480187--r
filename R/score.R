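#' Pathway-based distance score matrix
#'
#' Pools the per-pathway partitions into the pairwise disagreement score:
#' pathways that found only one cluster are excluded, and for each sample
#' pair the score is the proportion of the remaining ("voting") pathways
#' that assign the pair to different clusters,
#' `d(j1, j2) = #\{k : c^k_j1 != c^k_j2, m_k > 1\} / #\{k : m_k > 1\}`.
#' The result is symmetric with zero diagonal and entries in `[0, 1]`
#' that are exact multiples of `1 / n_voting_pathways`.
#'
#' When no pathway finds more than one cluster the score is identically
#' zero and carries no information (the regime of very small group
#' differences); this raises a `pathdist_degenerate_score` error whose
#' condition carries the all-zero matrix in `$score` for callers that want
#' to inspect it.
#'
#' @param clusterings A `pathway_clusterings` list from
#'   [cluster_all_pathways()] (or any list of `pathway_clustering` objects
#'   over one common sample set).
#' @return A numeric matrix of class `score_matrix` with attribute
#'   `n_voting_pathways`.
#' @export
#' @examples
#' ## two pathways that split 4 samples differently
#' pc <- function(nm, lab) {
#'   names(lab) <- paste0("s", 1:4)
#'   pathdist:::new_pathway_clustering(nm, lab, max(lab), 5L, "gmm", "EII",
#'                                     pathdist:::empty_bic_trace())
#' }
#' s <- score_matrix(list(pc("a", c(1L,1L,2L,2L)), pc("b", c(1L,2L,2L,2L))))
#' s["s1", "s3"]
score_matrix <- function(clusterings) {
  if (inherits(clusterings, "pathway_clustering")) clusterings <- list(clusterings)
  if (!length(clusterings)) abort("empty list of pathway clusterings.")
  labs <- lapply(clusterings, function(x) x$labels)
  ids <- names(labs[[1L]])
  n <- length(ids)
  ok <- vapply(labs, function(l) length(l) == n && identical(names(l), ids), logical(1))
  if (!all(ok)) abort("all pathway clusterings must share one sample set, in the same order.")

  mk <- vapply(clusterings, `[[`, integer(1), "m_k")
  voting <- which(mk > 1L)
  if (!length(voting)) {
    zero <- matrix(0, n, n, dimnames = list(ids, ids))
    abort(
      "no pathway identified more than one cluster; the distance score is identically 0.",
      class = "pathdist_degenerate_score",
      score = zero
    )
  }
  acc <- matrix(0, n, n)
  for (k in voting) {
    lab <- unname(labs[[k]])
    acc <- acc + (outer(lab, lab, `!=`) * 1)
  }
  s <- acc / length(voting)
  dimnames(s) <- list(ids, ids)
  structure(s, class = c("score_matrix", "matrix", "array"),
            n_voting_pathways = length(voting))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d samples, %d voting pathway(s)\n",
              nrow(x), attr(x, "n_voting_pathways")))
  print(utils::head(unclass_keep_dim(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE]))
  invisible(x)
}

#' Final distance: re-embed the score matrix as data
#'
#' The disagreement score is not itself a metric, so the score matrix is
#' treated as a new data matrix with one column per subject and the final
#' distance between two subjects is the Euclidean distance between their
#' columns (diagonal zeros included as coordinates).
#'
#' @param score A `score_matrix` (or any symmetric matrix with sample-id
#'   dimnames).
#' @return A symmetric numeric distance matrix with zero diagonal.
#' @export
final_distance <- function(score) {
  m <- unclass_keep_dim(as.matrix(score))
  check_distance_matrix(m, arg = "score")
  d <- as.matrix(dist(t(m), method = "euclidean"))
  dimnames(d) <- dimnames(m)
  d
}

#' Euclidean distance between samples, optionally pathway-filtered
#'
#' The comparator distances: with `gene_filter = NULL`, plain Euclidean
#' distance over all measured genes; with a gene-set collection, over the
#' union of all matched pathway genes, each gene counted once however many
#' pathways contain it.
#'
#' @param expr Gene-by-sample numeric matrix.
#' @param gene_filter Optional named list of gene-id vectors.
#' @return A symmetric numeric distance matrix over the samples.
#' @export
euclidean_distance <- function(expr, gene_filter = NULL) {
  check_expression_matrix(expr)
  if (!is.null(gene_filter)) {
    genes <- intersect(unique(unlist(gene_filter)), rownames(expr))
    if (!length(genes)) {
      abort("no gene of `gene_filter` is measured in `expr`.")
    }
    expr <- expr[genes, , drop = FALSE]
  }
  d <- as.matrix(dist(t(expr), method = "euclidean"))
  dimnames(d) <- list(colnames(expr), colnames(expr))
  d
}

#' One-call pathway-based distance pipeline
#'
#' Convenience wrapper: match the gene sets, cluster every pathway, build
#' the score matrix and its Euclidean re-embedding.
#'
#' @inheritParams cluster_all_pathways
#' @param min_size Minimum matched pathway size (see [match_pathways()]).
#' @return A list with `clusterings`, `score` (class `score_matrix`) and
#'   `distance` (final Euclidean re-embedding).
#' @export
pathway_distance <- function(expr, sets, options = gmm_options(),
                             downsample = NULL, min_size = 2L, seed = NULL) {
  matched <- match_pathways(expr, sets, min_size = min_size)
  cl <- cluster_all_pathways(expr, matched, options = options,
                             downsample = downsample, seed = seed)
  sc <- score_matrix(cl)
  list(clusterings = cl, score = sc, distance = final_distance(sc))
}
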