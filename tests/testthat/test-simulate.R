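test_that("synthetic gene-set collections are disjoint with deterministic names", {
  sets <- generate_synthetic_genesets(186, 10)
  expect_length(sets, 186)
  genes <- unlist(sets)
  expect_length(genes, 1860)
  expect_identical(anyDuplicated(genes), 0L)
  for (pair in list(c(1, 2), c(1, 186), c(50, 51))) {
    expect_length(intersect(sets[[pair[1]]], sets[[pair[2]]]), 0)
  }
  expect_identical(generate_synthetic_genesets(186, 10), sets)
  one <- generate_synthetic_genesets(1, 1)
  expect_identical(lengths(one), c(SIMPW001 = 1L))

  var_sets <- generate_synthetic_genesets_varsize(30, c(6, 80), seed = 1)
  expect_true(all(lengths(var_sets) >= 6 & lengths(var_sets) <= 80))
  expect_identical(anyDuplicated(unlist(var_sets)), 0L)
})

test_that("chosen pathway and gene counts follow half-up rounding of the fractions", {
  sets <- generate_synthetic_genesets(186, 10)
  ds <- simulate_dataset(sim_config(p_w = 0.2, p_g = 0.8, m_total = 2000), sets, seed = 1)
  expect_length(ds$chosen_pathways, 37)     # 0.2 * 186
  expect_true(all(lengths(ds$chosen_genes) == 8))   # 0.8 * 10
  expect_true(all(unlist(purrr::imap_lgl(ds$chosen_genes, function(g, pw) {
    all(g %in% sets[[pw]])
  }))))
  # ground truth is 40/40/40 in sample order
  expect_identical(unname(ds$truth), rep(1:3, each = 40L))
  expect_identical(dim(ds$expr), c(2000L, 120L))
})

test_that("fixed seeds give bit-identical datasets", {
  sets <- generate_synthetic_genesets(12, 10)
  a <- simulate_dataset(sim_config(delta = 1, rho = 0.5, m_total = 150), sets, seed = 42)
  b <- simulate_dataset(sim_config(delta = 1, rho = 0.5, m_total = 150), sets, seed = 42)
  expect_identical(a$expr, b$expr)
  expect_identical(a$chosen_pathways, b$chosen_pathways)
  c <- simulate_dataset(sim_config(delta = 1, rho = 0.5, m_total = 150), sets, seed = 43)
  expect_false(identical(a$expr, c$expr))
})

test_that("a null configuration carries no group signal", {
  sets <- generate_synthetic_genesets(10, 10)
  ds <- simulate_dataset(sim_config(delta = 0, p_w = 0.5, m_total = 120,
                                    group_sizes = c(70, 70, 60)), sets, seed = 3)
  chosen <- unique(unlist(ds$chosen_genes))
  g1 <- rowMeans(ds$expr[chosen, ds$truth == 1, drop = FALSE])
  g3 <- rowMeans(ds$expr[chosen, ds$truth == 3, drop = FALSE])
  se_gap <- sqrt(1 / 70 + 1 / 60)
  expect_true(all(abs(g1 - g3) < 4 * se_gap))
})

test_that("pooled variance of chosen genes matches the law-of-total-variance value", {
  sets <- generate_synthetic_genesets(20, 10)
  cfg <- sim_config(delta = 1.5, rho = 0, b = 1, p_w = 0.2, p_g = 0.8,
                    group_sizes = c(400, 400, 400), m_total = 300)
  ds <- simulate_dataset(cfg, sets, seed = 4)
  expect_equal(cfg$sigma2, 2.5)   # 1 + 2 * 1.5^2 / 3
  rep <- empirical_moment_check(ds)
  expect_true(all(abs(rep$gene_variances$z) < 3))
  expect_true(all(abs(rep$group_means$z) < 4))
})

test_that("within-group correlations recover rho on the Fisher scale", {
  sets <- generate_synthetic_genesets(6, 10)
  for (rho in c(0, 0.5, 0.9)) {
    cfg <- sim_config(delta = 1.5, rho = rho, p_w = 0.5, p_g = 0.8,
                      group_sizes = c(400, 400, 400), m_total = 100)
    ds <- simulate_dataset(cfg, sets, seed = 5)
    rep <- empirical_moment_check(ds)
    expect_gt(nrow(rep$pair_correlations), 0)
    expect_true(all(abs(rep$pair_correlations$z) < 3.5))
  }
})

test_that("background genes have the configured variance and no correlation", {
  sets <- generate_synthetic_genesets(4, 10)
  cfg <- sim_config(delta = 1, rho = 0, b = 2, p_w = 0.25, p_g = 0.5,
                    group_sizes = c(300, 300, 300), m_total = 60)
  ds <- simulate_dataset(cfg, sets, seed = 6)
  filler <- grep("^FILLER", rownames(ds$expr), value = TRUE)
  expect_length(filler, 60 - 40)
  v <- apply(ds$expr[filler, ], 1, var)
  target <- cfg$b * cfg$sigma2
  se <- target * sqrt(2 / (900 - 1))
  expect_true(all(abs(v - target) < 4 * se))
  cc <- cor(t(ds$expr[filler[1:10], ]))
  expect_true(all(abs(cc[upper.tri(cc)]) < 4 / sqrt(900)))
})

test_that("overlapping collections assign each gene one generating law", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"))
  expect_message(
    ds <- simulate_dataset(sim_config(p_w = 1, p_g = 1, delta = 2, m_total = 4,
                                      group_sizes = c(30, 30, 30)), sets, seed = 7),
    "first pathway"
  )
  expect_identical(nrow(ds$expr), 4L)
  # g2/g3 simulated once, under pathway A's law (chosen, shifted means)
  m1 <- rowMeans(ds$expr[, ds$truth == 1])
  m3 <- rowMeans(ds$expr[, ds$truth == 3])
  expect_true(all(m3[c("g1", "g2", "g3", "g4")] - m1[c("g1", "g2", "g3", "g4")] > 2))
})
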