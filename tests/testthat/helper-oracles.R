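# Independent brute-force reference implementations. These deliberately use
# plain double loops and no shared code with the package internals.

oracle_score_matrix <- function(label_list, m_list) {
  ids <- names(label_list[[1]])
  n <- length(ids)
  voting <- which(m_list > 1)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      cnt <- 0
      for (k in voting) {
        if (label_list[[k]][a] != label_list[[k]][b]) cnt <- cnt + 1
      }
      out[a, b] <- cnt / length(voting)
    }
  }
  out
}

oracle_column_distance <- function(m) {
  n <- ncol(m)
  out <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      out[a, b] <- sqrt(sum((m[, a] - m[, b])^2))
    }
  }
  out
}

oracle_connectivity <- function(labels, d, L) {
  n <- nrow(d)
  total <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    # full sorted neighbor list, ties by ascending index
    ord <- others[order(d[i, others], others)]
    for (j in seq_len(L)) {
      if (labels[ord[j]] != labels[i]) total <- total + 1 / j
    }
  }
  total
}

oracle_dunn <- function(labels, d) {
  n <- nrow(d)
  between <- Inf
  within <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (labels[a] == labels[b]) {
        within <- max(within, d[a, b])
      } else {
        between <- min(between, d[a, b])
      }
    }
  }
  if (within == 0) return(Inf)
  between / within
}

oracle_purity <- function(pred, truth) {
  total <- 0
  for (cl in unique(pred)) {
    members <- which(pred == cl)
    counts <- table(truth[members])
    total <- total + max(counts)
  }
  total / length(pred)
}

# random partition of n samples into at most k groups, every group nonempty
random_partition <- function(n, k) {
  repeat {
    lab <- sample.int(k, n, replace = TRUE)
    if (length(unique(lab)) >= 1) return(match(lab, unique(lab)))
  }
}

# random symmetric distance matrix with zero diagonal
random_distance <- function(n, ids = sprintf("s%02d", seq_len(n))) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  m
}

# fabricate a pathway_clustering without going through a mixture fit
fake_clustering <- function(name, labels, ids = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_along(labels))
  labels <- as.integer(labels)
  names(labels) <- ids
  pathdist:::new_pathway_clustering(name, labels,
                                    length(unique(labels)), 5L, "gmm", "EII",
                                    pathdist:::empty_bic_trace())
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# strip S3 class/attributes from a score matrix, keep dim + dimnames
unclass_keep <- function(m) {
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}
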