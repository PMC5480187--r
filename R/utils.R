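#' @importFrom rlang %||% abort warn inform
#' @importFrom mclust Mclust mclustBIC
#' @importFrom stats dist hclust cutree kmeans rnorm cor sd var cov
#' @importFrom utils head
NULL

# Deterministic sub-stream seed from a master seed and one or more indices.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master %% 2147483647L)
  for (i in idx) {
    h <- (h * 48271 + as.double(i) * 7919 + 1) %% 2147483647
  }
  as.integer(h)
}

# Half-up rounding (round() in R is banker's rounding; the chosen-pathway
# count must reproduce e.g. 0.2 * 186 -> 37 stably for all inputs).
round_half_up <- function(x) floor(x + 0.5)

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, min, max, x))
  }
  invisible(x)
}

check_expression_matrix <- function(values, arg = "expr") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples).", arg))
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort(sprintf("`%s` must carry gene ids as rownames and sample ids as colnames.", arg))
  }
  if (anyDuplicated(rownames(values))) {
    abort(sprintf("duplicated gene ids in `%s`.", arg))
  }
  if (anyDuplicated(colnames(values))) {
    abort(sprintf("duplicated sample ids in `%s`.", arg))
  }
  if (ncol(values) < 2L) {
    abort(sprintf("`%s` must have at least 2 samples.", arg))
  }
  if (!all(is.finite(values))) {
    abort(sprintf("`%s` contains missing or non-finite values.", arg))
  }
  invisible(values)
}

check_distance_matrix <- function(d, arg = "dist") {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d)) {
    abort(sprintf("`%s` must be a square numeric matrix.", arg))
  }
  if (!all(is.finite(d)) || any(d < 0)) {
    abort(sprintf("`%s` must be finite and nonnegative.", arg))
  }
  if (max(abs(d - t(d))) > 1e-8) {
    abort(sprintf("`%s` must be symmetric.", arg))
  }
  if (any(abs(diag(d)) > 1e-12)) {
    abort(sprintf("`%s` must have a zero diagonal.", arg))
  }
  invisible(d)
}

# Integer labels aligned to a sample id vector; accepts a named vector or a
# two-column data frame (sample_id, label).
as_labels <- function(x, sample_ids = NULL, arg = "labels") {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) abort(sprintf("`%s` data frame needs sample_id and label columns.", arg))
    lab <- as.integer(x[[2L]])
    names(lab) <- as.character(x[[1L]])
    x <- lab
  }
  if (!is.null(sample_ids)) {
    if (!is.null(names(x))) {
      if (!setequal(names(x), sample_ids)) {
        abort(sprintf("`%s` sample ids do not match the distance/feature matrix.", arg))
      }
      x <- x[sample_ids]
    } else if (length(x) != length(sample_ids)) {
      abort(sprintf("`%s` has %d labels for %d samples.", arg, length(x), length(sample_ids)))
    } else {
      names(x) <- sample_ids
    }
  }
  storage.mode(x) <- "integer"
  if (anyNA(x)) abort(sprintf("`%s` contains missing labels.", arg))
  x
}

# Relabel to consecutive integers 1..K in order of first appearance.
relabel_consecutive <- function(labels) {
  u <- unique(labels)
  match(labels, u)
}
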