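#' Options for cluster validation and optimal-k selection
#'
#' @param L Nearest neighbors per sample for the connectivity criterion
#'   (default 10, the convention of the cluster-validation literature the
#'   criterion comes from).
#' @param k_range Candidate cluster counts (default 2:5).
#' @param linkage Hierarchical linkage rule: `"average"` (default),
#'   `"single"` or `"complete"`.
#' @param kmeans_n_init K-means restarts (default 20).
#' @param seed Integer seed consumed by K-means.
#' @return A list of class `eval_options`.
#' @export
eval_options <- function(L = 10L, k_range = 2:5, linkage = "average",
                         kmeans_n_init = 20L, seed = NULL) {
  assert_scalar_number(L, "L", min = 1)
  k_range <- as.integer(k_range)
  if (min(k_range) < 2L) abort("`k_range` must start at 2 or above.")
  linkage <- match.arg(linkage, c("average", "single", "complete"))
  structure(list(L = as.integer(L), k_range = k_range, linkage = linkage,
                 kmeans_n_init = as.integer(kmeans_n_init), seed = seed),
            class = "eval_options")
}

#' Connectivity criterion of a partition
#'
#' For each sample, the other samples are ranked by increasing distance
#' (ties broken by ascending sample index, which keeps the criterion
#' deterministic on heavily tied score matrices) and a penalty of `1/j` is
#' added whenever the j-th nearest neighbor (j = 1..L) sits in a different
#' cluster. Small values mean the partition respects the neighborhood
#' structure; the criterion is minimized over candidate k.
#'
#' @param labels Integer cluster labels (named vector or two-column data
#'   frame).
#' @param dist Symmetric distance matrix over the same samples.
#' @param L Number of nearest neighbors per sample.
#' @return A single nonnegative number.
#' @export
connectivity <- function(labels, dist, L = 10L) {
  check_distance_matrix(dist)
  n <- nrow(dist)
  labels <- as_labels(labels, sample_ids = rownames(dist))
  assert_scalar_number(L, "L", min = 1, max = n - 1)
  total <- 0
  inv_j <- 1 / seq_len(L)
  for (i in seq_len(n)) {
    ord <- order(dist[i, -i], seq_len(n - 1L))   # tie-break: ascending index
    nn <- (seq_len(n)[-i])[ord][seq_len(L)]
    total <- total + sum(inv_j[labels[nn] != labels[i]])
  }
  total
}

#' Dunn index of a partition
#'
#' Minimum between-cluster pairwise distance divided by maximum
#' within-cluster pairwise distance; large for compact, well-separated
#' partitions. When every cluster is a singleton the denominator is zero
#' and `Inf` is returned.
#'
#' @inheritParams connectivity
#' @return A single nonnegative number (possibly `Inf`).
#' @export
dunn_index <- function(labels, dist) {
  check_distance_matrix(dist)
  labels <- as_labels(labels, sample_ids = rownames(dist))
  if (length(unique(labels)) < 2L) abort("Dunn index needs at least 2 clusters.")
  same <- outer(labels, labels, `==`)
  ut <- upper.tri(dist)
  between <- dist[ut & !same]
  within <- dist[ut & same]
  max_within <- if (length(within)) max(within) else 0
  min_between <- min(between)
  if (max_within == 0) return(Inf)
  min_between / max_within
}

#' Purity of a partition against a reference grouping
#'
#' Each predicted cluster is credited with its most frequent true label;
#' purity is the total credit over N. Equals 1 exactly when every predicted
#' cluster is contained in a single true class, and is invariant to
#' relabeling on either side.
#'
#' @param labels Predicted integer labels (named vector or two-column data
#'   frame).
#' @param truth Reference labels over the same samples.
#' @return A number in (0, 1].
#' @export
purity <- function(labels, truth) {
  labels <- as_labels(labels, arg = "labels")
  truth <- as_labels(truth, arg = "truth")
  if (!is.null(names(labels)) && !is.null(names(truth))) {
    if (!setequal(names(labels), names(truth))) {
      abort("`labels` and `truth` cover different samples.")
    }
    truth <- truth[names(labels)]
  } else if (length(labels) != length(truth)) {
    abort("`labels` and `truth` have different lengths and no sample ids to align by.")
  }
  tab <- table(labels, truth)
  sum(apply(tab, 1L, max)) / length(labels)
}

#' K-means partition of a feature matrix
#'
#' Best-of-`kmeans_n_init` restarts of the squared-error K-means, seeded for
#' reproducibility. Rows are samples.
#'
#' @param data Numeric matrix, one row per sample.
#' @param k Number of clusters.
#' @param opts An [eval_options()] list.
#' @return A named integer vector of labels `1..k`.
#' @export
kmeans_cluster <- function(data, k, opts = eval_options()) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (k > n) abort(sprintf("k = %d exceeds the %d samples.", k, n))
  ids <- rownames(data) %||% as.character(seq_len(n))
  if (k == n) {
    # one sample per cluster; zero within-cluster sum of squares
    return(stats::setNames(seq_len(n), ids))
  }
  seed <- opts$seed %||% 0L
  fit <- withr::with_seed(seed, suppressWarnings(
    kmeans(data, centers = k, nstart = opts$kmeans_n_init, iter.max = 100L)
  ))
  labels <- as.integer(fit$cluster)
  names(labels) <- ids
  labels
}

#' Hierarchical-clustering partition of a distance matrix
#'
#' Agglomerative clustering (stats::hclust) under the configured linkage,
#' cut to k clusters. Deterministic for a given input.
#'
#' @param dist Symmetric distance matrix.
#' @param k Number of clusters.
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return A named integer vector of labels `1..k`.
#' @export
hierarchical_cluster <- function(dist, k, linkage = "average") {
  check_distance_matrix(dist)
  if (k > nrow(dist)) abort(sprintf("k = %d exceeds the %d samples.", k, nrow(dist)))
  hc <- hclust(stats::as.dist(dist), method = linkage)
  labels <- cutree(hc, k = k)
  labels <- stats::setNames(as.integer(labels), rownames(dist))
  labels
}

#' Select the number of clusters by the connectivity criterion
#'
#' For each k in `k_range`, partitions the samples with the requested
#' clustering method and scores the partition with the connectivity
#' criterion against `dist`; returns the k minimizing connectivity (ties
#' broken toward the largest tied k, see Details) together with the full
#' trace and the partitions. For the
#' pathway-based score, pass the score matrix columns as `features` and the
#' final (re-embedded) distance as `dist`; for plain Euclidean comparators
#' the same distance matrix plays both roles, K-means then operating on the
#' distance columns as feature vectors.
#'
#' @details
#' When groups are well separated every sample's L nearest neighbors fall
#' inside its own group, so connectivity is exactly zero for every k at or
#' below the true group count and the criterion ties. Because merging
#' clusters can only remove penalties (for nested hierarchical cuts the
#' criterion is nondecreasing in k), breaking ties toward the smallest k
#' would systematically underestimate the cluster count exactly when the
#' signal is strongest; ties are therefore broken toward the largest k
#' attaining the minimum (within a 1e-9 tolerance).
#'
#' @param dist Symmetric distance matrix (neighbor structure + hierarchical
#'   clustering input).
#' @param features Numeric matrix with one column per sample, the K-means
#'   input; defaults to `dist` itself.
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param opts An [eval_options()] list.
#' @return A list of class `k_selection`: `k` (selected), `trace` (tibble
#'   with `k`, `connectivity`, `dunn`), `partition` (labels at the selected
#'   k) and `partitions` (all candidates).
#' @export
select_k_connectivity <- function(dist, features = NULL,
                                  method = c("kmeans", "hierarchical"),
                                  opts = eval_options()) {
  method <- match.arg(method)
  check_distance_matrix(dist)
  n <- nrow(dist)
  features <- features %||% dist
  if (max(opts$k_range) > n - 1L) {
    abort("`k_range` must stay below the number of samples.")
  }
  ks <- opts$k_range
  partitions <- vector("list", length(ks))
  conn <- dunn <- numeric(length(ks))
  for (i in seq_along(ks)) {
    part <- tryCatch(
      switch(method,
        kmeans = kmeans_cluster(t(features), ks[i], opts),
        hierarchical = hierarchical_cluster(dist, ks[i], opts$linkage)
      ),
      error = function(e) NULL   # e.g. k exceeds the distinct points
    )
    partitions[i] <- list(part)
    if (is.null(part)) {
      conn[i] <- Inf
      dunn[i] <- NA_real_
    } else {
      conn[i] <- connectivity(part, dist, L = min(opts$L, n - 1L))
      dunn[i] <- dunn_index(part, dist)
    }
  }
  if (all(is.infinite(conn))) abort("no candidate k produced a partition.")
  # Ties are broken toward the largest k attaining the minimum: merging
  # clusters can only remove 1/j penalties (for nested cuts connectivity is
  # nondecreasing in k), so the criterion is weakly biased toward small k;
  # among partitions that respect the neighborhood structure equally well,
  # the finest one exposes the most structure. Tolerance absorbs float noise
  # in sums of 1/j.
  best <- max(which(conn <= min(conn) + 1e-9))
  structure(
    list(k = ks[best],
         trace = tibble::tibble(k = ks, connectivity = conn, dunn = dunn),
         partition = partitions[[best]],
         partitions = stats::setNames(partitions, paste0("k", ks)),
         method = method),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> method = %s, selected k = %d\n", x$method, x$k))
  print(x$trace)
  invisible(x)
}

#' Evaluate a partition (and optionally compare against ground truth)
#'
#' @param labels Integer labels (named vector or two-column data frame).
#' @param dist Distance matrix over the same samples.
#' @param truth Optional reference labels.
#' @param L Connectivity neighbor count.
#' @return A one-row tibble with `k`, `connectivity`, `dunn` and (when
#'   `truth` is given) `purity`.
#' @export
evaluate_partition <- function(labels, dist, truth = NULL, L = 10L) {
  labels <- as_labels(labels, sample_ids = rownames(dist))
  out <- tibble::tibble(
    k = length(unique(labels)),
    connectivity = connectivity(labels, dist, L = min(L, nrow(dist) - 1L)),
    dunn = if (length(unique(labels)) > 1L) dunn_index(labels, dist) else NA_real_
  )
  if (!is.null(truth)) out$purity <- purity(labels, truth)
  out
}
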