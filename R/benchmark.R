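#' Benchmark configuration
#'
#' A grid over the simulation knobs crossed with the distance methods and
#' clustering algorithms to compare. Each grid cell is simulated
#' `replicates` times; per-replicate seeds are derived from `seed`, the
#' cell index and the replicate index, so any single replicate can be
#' re-run in isolation and cells may be evaluated in any order.
#'
#' @param delta,rho,b,p_g,p_w Numeric vectors defining the grid.
#' @param replicates Replicates per cell (default 10 for desk runs; 100
#'   matches the full published-scale experiment).
#' @param methods Distance methods: subset of `"euclid_all"`,
#'   `"euclid_pathway_genes"`, `"pathway_score"`,
#'   `"pathway_score_downsampled"`.
#' @param clusterings Clustering algorithms: subset of `"kmeans"`,
#'   `"hierarchical"`.
#' @param eval An [eval_options()] list.
#' @param gmm A [gmm_options()] list.
#' @param downsample A [downsample_options()] list (used by the
#'   downsampled method only).
#' @param m_total Total simulated genes (filler included).
#' @param group_sizes Group sizes for the simulated cohorts.
#' @param true_k The planted number of groups counted as a success
#'   (default 3).
#' @param seed Master seed.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(delta = 1.5, rho = 0, b = 1, p_g = 0.8, p_w = 0.2,
                             replicates = 10L,
                             methods = c("euclid_all", "euclid_pathway_genes",
                                         "pathway_score"),
                             clusterings = c("kmeans", "hierarchical"),
                             eval = eval_options(), gmm = gmm_options(),
                             downsample = downsample_options(),
                             m_total = 22148L, group_sizes = c(40L, 40L, 40L),
                             true_k = 3L, seed = 1L) {
  methods <- match.arg(methods, c("euclid_all", "euclid_pathway_genes",
                                  "pathway_score", "pathway_score_downsampled"),
                       several.ok = TRUE)
  clusterings <- match.arg(clusterings, c("kmeans", "hierarchical"),
                           several.ok = TRUE)
  assert_scalar_number(replicates, "replicates", min = 1)
  structure(list(grid = tidyr::expand_grid(delta = delta, rho = rho, b = b,
                                           p_g = p_g, p_w = p_w),
                 replicates = as.integer(replicates), methods = methods,
                 clusterings = clusterings, eval = eval, gmm = gmm,
                 downsample = downsample, m_total = as.integer(m_total),
                 group_sizes = as.integer(group_sizes),
                 true_k = as.integer(true_k), seed = as.integer(seed)),
            class = "benchmark_config")
}

BENCHMARK_METHODS <- c("euclid_all", "euclid_pathway_genes",
                       "pathway_score", "pathway_score_downsampled")

#' Compute one distance method on a simulated dataset
#'
#' @param dataset A `sim_dataset`.
#' @param sets The pathway collection the dataset was simulated over.
#' @param method One of the benchmark distance methods.
#' @param config A `benchmark_config` (for GMM/downsampling options).
#' @param seed Seed for the stochastic stages.
#' @return A list with `dist` (distance matrix) and `features` (matrix with
#'   one column per sample fed to K-means).
#' @keywords internal
benchmark_distance <- function(dataset, sets, method, config, seed) {
  expr <- dataset$expr
  switch(method,
    euclid_all = {
      d <- euclidean_distance(expr)
      list(dist = d, features = d)
    },
    euclid_pathway_genes = {
      d <- euclidean_distance(expr, gene_filter = sets)
      list(dist = d, features = d)
    },
    pathway_score = {
      cl <- cluster_all_pathways(expr, sets, options = config$gmm, seed = seed)
      sc <- score_matrix(cl)
      list(dist = final_distance(sc), features = unclass_keep_dim(sc))
    },
    pathway_score_downsampled = {
      cl <- cluster_all_pathways(expr, sets, options = config$gmm,
                                 downsample = config$downsample, seed = seed)
      sc <- score_matrix(cl)
      list(dist = final_distance(sc), features = unclass_keep_dim(sc))
    },
    abort(sprintf("unknown method '%s'.", method))
  )
}

#' Run the simulation benchmark
#'
#' For every grid cell and replicate: simulate a labeled dataset, compute
#' each requested distance, select the number of clusters by the
#' connectivity criterion for each clustering algorithm, cluster at the
#' selected k, and score the partition's purity against the planted groups.
#' Per-replicate failures (e.g. a degenerate all-zero score at very small
#' `delta`) are recorded with an error message and excluded from the rates,
#' never silently dropped.
#'
#' @param config A [benchmark_config()] list.
#' @param sets Pathway collection used both to simulate and to score.
#' @return A list of class `benchmark_report` with `records` (one tibble
#'   row per cell x replicate x method x clustering) and `summary`
#'   (success rate of selecting `true_k`, median purity, failure counts).
#' @export
run_benchmark <- function(config, sets) {
  stopifnot(inherits(config, "benchmark_config"))
  grid <- config$grid
  rec <- list()
  for (cell in seq_len(nrow(grid))) {
    g <- grid[cell, ]
    for (rep in seq_len(config$replicates)) {
      seed_r <- derive_seed(config$seed, cell, rep)
      cfg <- sim_config(delta = g$delta, p_w = g$p_w, p_g = g$p_g,
                        rho = g$rho, b = g$b,
                        group_sizes = config$group_sizes,
                        m_total = config$m_total)
      ds <- simulate_dataset(cfg, sets, seed = seed_r)
      for (method in config$methods) {
        m_id <- match(method, BENCHMARK_METHODS)
        dm <- tryCatch(
          benchmark_distance(ds, sets, method, config,
                             seed = derive_seed(seed_r, m_id)),
          error = function(e) e
        )
        for (clus in config$clusterings) {
          row <- tibble::tibble(
            cell = cell, delta = g$delta, rho = g$rho, b = g$b,
            p_g = g$p_g, p_w = g$p_w, replicate = rep,
            method = method, clustering = clus,
            selected_k = NA_integer_, purity = NA_real_,
            success = NA, error = NA_character_,
            trace = list(NULL)
          )
          if (inherits(dm, "error")) {
            row$error <- conditionMessage(dm)
          } else {
            res <- tryCatch({
              opts <- config$eval
              opts$seed <- derive_seed(seed_r, m_id,
                                       match(clus, c("kmeans", "hierarchical")))
              sel <- select_k_connectivity(dm$dist, features = dm$features,
                                           method = clus, opts = opts)
              list(k = sel$k, purity = purity(sel$partition, ds$truth),
                   trace = sel$trace)
            }, error = function(e) e)
            if (inherits(res, "error")) {
              row$error <- conditionMessage(res)
            } else {
              row$selected_k <- res$k
              row$purity <- res$purity
              row$success <- res$k == config$true_k
              row$trace <- list(res$trace)
            }
          }
          rec[[length(rec) + 1L]] <- row
        }
      }
    }
  }
  records <- dplyr::bind_rows(rec)
  summary <- records |>
    dplyr::group_by(.data$delta, .data$rho, .data$b, .data$p_g, .data$p_w,
                    .data$method, .data$clustering) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      failures = sum(!is.na(.data$error)),
      success_rate = mean(.data$success[is.na(.data$error)]),
      median_purity = stats::median(.data$purity[is.na(.data$error)]),
      iqr_purity = stats::IQR(.data$purity[is.na(.data$error)]),
      .groups = "drop"
    )
  structure(list(records = records, summary = summary, config = config),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d records over %d cell(s)\n",
              nrow(x$records), nrow(x$config$grid)))
  print(x$summary)
  invisible(x)
}
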