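#' Simulation configuration
#'
#' Describes one cell of the simulation design: three sample groups with
#' mean shifts `-delta / 0 / +delta` on the differentially expressed
#' ("chosen") genes, a fraction `p_w` of pathways associated with the
#' grouping, a fraction `p_g` of each chosen pathway's members perturbed,
#' equicovariance `rho` between genes of the same pathway, and a background
#' variance factor `b` for all non-chosen genes. Chosen genes have
#' within-group variance 1, so their pooled marginal variance across the
#' three equal groups is `sigma^2 = 1 + 2*delta^2/3`; non-chosen genes are
#' simulated with marginal variance `b * sigma^2` in every group.
#'
#' @param delta Group mean shift (>= 0).
#' @param p_w Fraction of pathways associated with the grouping, in (0, 1].
#' @param p_g Fraction of member genes perturbed per chosen pathway, in
#'   (0, 1].
#' @param rho Within-pathway pairwise covariance, in \[0, 1).
#' @param b Background variance factor (>= 1).
#' @param group_sizes Integer vector of length 3 (default `c(40, 40, 40)`).
#' @param m_total Total measured genes including unannotated filler
#'   (default 22148, an expression-array-sized gene universe); filler genes
#'   are independent background noise.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(delta = 1.5, p_w = 0.2, p_g = 0.8, rho = 0, b = 1,
                       group_sizes = c(40L, 40L, 40L), m_total = 22148L,
                       seed = NULL) {
  assert_scalar_number(delta, "delta", min = 0)
  assert_scalar_number(p_w, "p_w", min = 1e-12, max = 1)
  assert_scalar_number(p_g, "p_g", min = 1e-12, max = 1)
  assert_scalar_number(rho, "rho", min = 0, max = 1 - 1e-9)
  assert_scalar_number(b, "b", min = 1)
  if (length(group_sizes) != 3L || any(group_sizes < 1)) {
    abort("`group_sizes` must be three positive integers.")
  }
  structure(list(delta = delta, p_w = p_w, p_g = p_g, rho = rho, b = b,
                 group_sizes = as.integer(group_sizes),
                 m_total = as.integer(m_total), seed = seed,
                 sigma2 = 1 + 2 * delta^2 / 3),
            class = "sim_config")
}

#' Generate disjoint synthetic gene sets
#'
#' Equally sized, non-overlapping pathways over a synthetic gene universe —
#' the low-dimension simulation design (e.g. 186 pathways of 10 genes).
#' Naming is deterministic: sets `PREFIX001..`, genes `PREFIXg00001..`.
#'
#' @param n_pathways Number of sets.
#' @param set_size Genes per set.
#' @param prefix Name prefix (default `"SIMPW"`).
#' @return A named list of disjoint character vectors.
#' @export
#' @examples
#' sets <- generate_synthetic_genesets(186, 10)
#' length(unique(unlist(sets)))   # 1860 genes, no overlap
generate_synthetic_genesets <- function(n_pathways, set_size, prefix = "SIMPW") {
  assert_scalar_number(n_pathways, "n_pathways", min = 1)
  assert_scalar_number(set_size, "set_size", min = 1)
  genes <- sprintf("%sg%05d", prefix, seq_len(n_pathways * set_size))
  sets <- split(genes, rep(seq_len(n_pathways), each = set_size))
  names(sets) <- sprintf("%s%03d", prefix, seq_len(n_pathways))
  sets
}

#' Generate synthetic gene sets with variable sizes
#'
#' A KEGG-like collection: set sizes drawn log-uniformly between
#' `size_range[1]` and `size_range[2]` (real metabolic-pathway collections
#' span roughly 6 to a few hundred genes), sets disjoint over a synthetic
#' universe. Used to exercise the high-dimension regime without shipping a
#' licensed gene-set download; the collection is synthetic and labelled as
#' such.
#'
#' @param n_pathways Number of sets.
#' @param size_range Length-2 integer vector, min and max set size.
#' @param prefix Name prefix.
#' @param seed Integer seed for the size draws.
#' @return A named list of disjoint character vectors.
#' @export
generate_synthetic_genesets_varsize <- function(n_pathways, size_range = c(6L, 80L),
                                                prefix = "SYNKEGG", seed = 0L) {
  assert_scalar_number(n_pathways, "n_pathways", min = 1)
  sizes <- withr::with_seed(seed, {
    round(exp(stats::runif(n_pathways, log(size_range[1]), log(size_range[2]))))
  })
  total <- sum(sizes)
  genes <- sprintf("%sg%05d", prefix, seq_len(total))
  idx <- rep(seq_len(n_pathways), times = sizes)
  sets <- split(genes, idx)
  names(sets) <- sprintf("%s%03d", prefix, seq_len(n_pathways))
  sets
}

#' Simulate a labeled expression dataset with block covariance
#'
#' Samples three groups (sizes from the config) of subjects. A fraction
#' `p_w` of the pathways is chosen to be associated with the grouping; in
#' each chosen pathway a fraction `p_g` of member genes (at least one) is
#' chosen to be differentially expressed with group means
#' `-delta / 0 / +delta` and within-group variance 1. All other pathway
#' genes have mean 0 and marginal variance `b * sigma^2`. Genes within one
#' pathway share pairwise covariance `rho` (chosen and non-chosen alike);
#' pathways are mutually independent blocks, and filler genes outside every
#' pathway are independent background noise with variance `b * sigma^2`.
#'
#' Within a pathway the covariance is `rho * J + diag(v_i - rho)` with
#' `v_i` the per-gene variance; positive definiteness requires
#' `min(v_i) > rho`, which is asserted (it holds for every valid config
#' since chosen genes have `v = 1 > rho`).
#'
#' A gene belonging to several pathways is generated under the first
#' pathway (collection order) that contains it; later pathways reuse its
#' values, so every gene has exactly one generating law.
#'
#' @param config A [sim_config()] list.
#' @param sets Named list of gene-id vectors (pathway collection).
#' @param seed Integer seed overriding `config$seed`.
#' @return A list of class `sim_dataset`: `expr` (genes x samples matrix),
#'   `truth` (named integer labels 1..3), `chosen_pathways`,
#'   `chosen_genes` (named list, one vector per chosen pathway), `config`.
#' @export
simulate_dataset <- function(config = sim_config(), sets, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(sets) == 0L) abort("`sets` must contain at least one pathway.")
  seed <- seed %||% config$seed %||% 0L
  gs <- config$group_sizes
  n <- sum(gs)
  sample_ids <- sprintf("S%03d", seq_len(n))
  truth <- stats::setNames(rep(1:3, times = gs), sample_ids)
  group_mu <- c(-config$delta, 0, config$delta)
  sigma2 <- config$sigma2
  bg_var <- config$b * sigma2
  rho <- config$rho

  # first-pathway ownership for genes shared across pathways
  all_genes <- unlist(sets, use.names = FALSE)
  owner <- !duplicated(all_genes)
  covered_genes <- all_genes[owner]
  owned <- split(all_genes[owner], rep(seq_along(sets), lengths(sets))[owner])
  n_overlap <- sum(!owner)
  if (n_overlap > 0L) {
    inform(sprintf("%d gene-pathway memberships beyond the first owner; generating law fixed by first pathway.", n_overlap))
  }

  n_filler <- max(0L, config$m_total - length(covered_genes))
  filler_ids <- if (n_filler > 0L) sprintf("FILLER%05d", seq_len(n_filler)) else character(0)

  withr::with_seed(seed, {
    k_total <- length(sets)
    n_chosen <- max(1L, round_half_up(config$p_w * k_total))
    chosen_idx <- sort(sample.int(k_total, n_chosen))
    chosen_pathways <- names(sets)[chosen_idx]
    chosen_genes <- lapply(chosen_idx, function(k) {
      members <- sets[[k]]
      n_g <- max(1L, round_half_up(config$p_g * length(members)))
      sort(sample(members, n_g))
    })
    names(chosen_genes) <- chosen_pathways
    # generating role: chosen iff chosen in the owning pathway
    chosen_set <- unlist(lapply(seq_along(chosen_idx), function(i) {
      intersect(chosen_genes[[i]], owned[[as.character(chosen_idx[i])]] %||% character(0))
    }), use.names = FALSE)

    expr <- matrix(NA_real_, length(covered_genes) + n_filler, n,
                   dimnames = list(c(covered_genes, filler_ids), sample_ids))
    for (k in seq_along(sets)) {
      g <- owned[[as.character(k)]]
      if (is.null(g) || !length(g)) next
      v <- ifelse(g %in% chosen_set, 1, bg_var)
      if (min(v) <= rho) {
        abort(sprintf("pathway %s: within-pathway covariance rho = %g is not below the smallest gene variance %g; covariance not positive definite.",
                      names(sets)[k], rho, min(v)))
      }
      p <- length(g)
      block <- matrix(rnorm(p * n), p, n) * sqrt(v - rho)
      if (rho > 0) {
        shared <- rnorm(n, 0, sqrt(rho))
        block <- block + rep(shared, each = p)
      }
      mu <- matrix(0, p, n)
      is_chosen <- g %in% chosen_set
      if (any(is_chosen)) {
        mu[is_chosen, ] <- rep(group_mu[truth], each = sum(is_chosen))
      }
      expr[g, ] <- block + mu
    }
    if (n_filler > 0L) {
      expr[filler_ids, ] <- matrix(rnorm(n_filler * n, 0, sqrt(bg_var)), n_filler, n)
    }
  })

  structure(list(expr = expr, truth = truth,
                 chosen_pathways = chosen_pathways,
                 chosen_genes = chosen_genes,
                 config = config, seed = seed),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d genes x %d samples; %d chosen pathway(s); delta = %g, rho = %g, b = %g\n",
              nrow(x$expr), ncol(x$expr), length(x$chosen_pathways),
              x$config$delta, x$config$rho, x$config$b))
  invisible(x)
}

#' Empirical moment checks for a simulated dataset
#'
#' Compares the realized dataset against its configured generating law:
#' per-group means of chosen genes (target `-delta / 0 / +delta`), pooled
#' marginal variances of chosen genes (target `sigma^2 = 1 + 2*delta^2/3`,
#' z-scored with the exact fourth-moment Monte-Carlo standard error of the
#' mixture), and within-group correlations of same-pathway chosen gene
#' pairs (target `rho / sqrt(v_i v_j) = rho` for unit-variance chosen
#' genes, on the Fisher-z scale).
#'
#' @param dataset A `sim_dataset`.
#' @return A list of class `moment_report` with tibbles `gene_variances`
#'   (`gene`, `variance`, `target`, `se`, `z`), `group_means` (`gene`,
#'   `group`, `mean`, `target`, `se`, `z`) and `pair_correlations`
#'   (`pathway`, `gene1`, `gene2`, `r`, `target`, `z` on the Fisher scale).
#' @export
empirical_moment_check <- function(dataset) {
  stopifnot(inherits(dataset, "sim_dataset"))
  cfg <- dataset$config
  expr <- dataset$expr
  truth <- dataset$truth
  n <- length(truth)
  chosen <- unique(unlist(dataset$chosen_genes))
  chosen <- intersect(chosen, rownames(expr))

  # pooled variance: exact MC standard error from the mixture's 4th moment
  delta <- cfg$delta
  sigma2 <- cfg$sigma2
  mu4 <- (2 * (delta^4 + 6 * delta^2 + 3) + 3) / 3
  se_var <- sqrt((mu4 - sigma2^2) / n)
  v <- apply(expr[chosen, , drop = FALSE], 1L, var)
  gene_variances <- tibble::tibble(
    gene = chosen, variance = unname(v), target = sigma2,
    se = se_var, z = (unname(v) - sigma2) / se_var
  )

  group_mu <- c(-delta, 0, delta)
  gm <- purrr::map_dfr(1:3, function(g) {
    cols <- which(truth == g)
    m <- rowMeans(expr[chosen, cols, drop = FALSE])
    tibble::tibble(gene = chosen, group = g, mean = unname(m),
                   target = group_mu[g], se = 1 / sqrt(length(cols)),
                   z = (unname(m) - group_mu[g]) * sqrt(length(cols)))
  })

  pair_correlations <- purrr::map_dfr(names(dataset$chosen_genes), function(pw) {
    g <- intersect(dataset$chosen_genes[[pw]], chosen)
    if (length(g) < 2L) return(tibble::tibble())
    centered <- expr[g, , drop = FALSE]
    for (grp in 1:3) {
      cols <- which(truth == grp)
      centered[, cols] <- centered[, cols] - rowMeans(centered[, cols, drop = FALSE])
    }
    cc <- cor(t(centered))
    pairs <- which(upper.tri(cc), arr.ind = TRUE)
    se_z <- 1 / sqrt((n - 3) - 3)   # 3 group means partialled out
    tibble::tibble(
      pathway = pw,
      gene1 = g[pairs[, 1L]], gene2 = g[pairs[, 2L]],
      r = cc[pairs], target = cfg$rho,
      z = (atanh(cc[pairs]) - atanh(cfg$rho)) / se_z
    )
  })

  structure(list(gene_variances = gene_variances, group_means = gm,
                 pair_correlations = pair_correlations, config = cfg),
            class = "moment_report")
}

#' @export
print.moment_report <- function(x, ...) {
  cat(sprintf("<moment_report> %d chosen genes; max |z| variance = %.2f, mean = %.2f, correlation = %.2f\n",
              nrow(x$gene_variances), max(abs(x$gene_variances$z)),
              max(abs(x$group_means$z)),
              if (nrow(x$pair_correlations)) max(abs(x$pair_correlations$z)) else NA_real_))
  invisible(x)
}
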