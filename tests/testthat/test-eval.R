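test_that("connectivity matches hand-computed neighbor lists", {
  # 4 samples; L = 1: nearest neighbors are 1<->3 and 2<->4
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "c"] <- d["c", "a"] <- 1
  d["b", "d"] <- d["d", "b"] <- 2
  d["a", "d"] <- d["d", "a"] <- 4
  d["a", "b"] <- d["b", "a"] <- 5
  d["b", "c"] <- d["c", "b"] <- 6
  d["c", "d"] <- d["d", "c"] <- 7
  expect_equal(connectivity(c(a = 1, c = 1, b = 2, d = 2), d, L = 1), 0)
  expect_equal(connectivity(c(a = 1, b = 1, c = 2, d = 2), d, L = 1), 4)
  # all samples in one cluster -> no cross-cluster neighbor
  expect_equal(connectivity(stats::setNames(rep(1, 4), letters[1:4]), d, L = 3), 0)
  expect_error(connectivity(c(a = 1, b = 1, c = 2, d = 2), d, L = 4), "L")
})

test_that("connectivity, Dunn and purity match brute-force implementations", {
  set.seed(404)
  for (rep in 1:30) {
    n <- sample(10:20, 1)
    d <- random_distance(n)
    lab <- random_partition(n, sample(2:5, 1))
    named <- stats::setNames(lab, rownames(d))
    L <- sample(1:(n - 1), 1)
    expect_equal(connectivity(named, d, L = L), oracle_connectivity(lab, d, L),
                 tolerance = 1e-12)
    if (length(unique(lab)) >= 2) {
      expect_equal(dunn_index(named, d), oracle_dunn(lab, d), tolerance = 1e-12)
    }
    truth <- random_partition(n, 3)
    expect_equal(purity(named, stats::setNames(truth, rownames(d))),
                 oracle_purity(lab, truth), tolerance = 1e-12)
  }
})

test_that("Dunn index handles hand cases and the degenerate denominator", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 1
  d["c", "d"] <- d["d", "c"] <- 2
  d["a", "c"] <- d["c", "a"] <- 4
  d["a", "d"] <- d["d", "a"] <- 5
  d["b", "c"] <- d["c", "b"] <- 6
  d["b", "d"] <- d["d", "b"] <- 4.5
  expect_equal(dunn_index(c(a = 1, b = 1, c = 2, d = 2), d), 4 / 2)
  # two singletons: zero within-cluster spread -> +Inf sentinel
  d2 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_identical(dunn_index(c(x = 1, y = 2), d2), Inf)
  expect_error(dunn_index(c(x = 1, y = 1), d2), "2 clusters")
})

test_that("purity is relabel-invariant and 1 iff clusters refine true classes", {
  truth <- c(s1 = 1L, s2 = 1L, s3 = 2L, s4 = 2L, s5 = 3L)
  # same partition, arbitrary labels
  expect_equal(purity(c(s1 = 9L, s2 = 9L, s3 = 4L, s4 = 4L, s5 = 7L), truth), 1)
  # worked example: clusters {s1,s2,s3}, {s4,s5} -> (2 + 1)/5
  expect_equal(purity(c(s1 = 1L, s2 = 1L, s3 = 1L, s4 = 2L, s5 = 2L), truth), 0.6)
  # refinement (splitting a true class) still gives 1
  expect_equal(purity(c(s1 = 1L, s2 = 2L, s3 = 3L, s4 = 3L, s5 = 4L), truth), 1)
  # property: purity == 1 exactly when every cluster maps into one true class
  set.seed(55)
  for (rep in 1:50) {
    n <- 20
    truth_r <- random_partition(n, 3)
    pred_r <- random_partition(n, 4)
    p <- purity(pred_r, truth_r)
    refines <- all(vapply(unique(pred_r), function(cl) {
      length(unique(truth_r[pred_r == cl])) == 1
    }, logical(1)))
    expect_identical(p == 1, refines)
  }
})

test_that("kmeans wrapper recovers planted blobs and handles degenerate k", {
  set.seed(66)
  x <- matrix(c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)), ncol = 1)
  rownames(x) <- sprintf("s%02d", 1:40)
  lab <- kmeans_cluster(x, 2, eval_options(seed = 1))
  expect_equal(purity(lab, stats::setNames(rep(1:2, each = 20), rownames(x))), 1)
  # k = N: singletons with zero objective
  small <- x[1:5, , drop = FALSE]
  lab_n <- kmeans_cluster(small, 5, eval_options(seed = 1))
  expect_identical(sort(unname(lab_n)), 1:5)
  # duplicate rows get identical assignments
  dup <- rbind(x[1:3, , drop = FALSE], x[1:3, , drop = FALSE])
  rownames(dup) <- sprintf("d%d", 1:6)
  lab_d <- kmeans_cluster(dup, 2, eval_options(seed = 1))
  expect_identical(unname(lab_d[1:3]), unname(lab_d[4:6]))
  expect_error(kmeans_cluster(small, 9, eval_options()), "exceeds")
})

test_that("hierarchical clustering cuts the chain where the big gap is", {
  d <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  d[1, 2] <- d[2, 1] <- 1
  d[2, 3] <- d[3, 2] <- 10
  d[3, 4] <- d[4, 3] <- 1
  d[1, 3] <- d[3, 1] <- 11
  d[2, 4] <- d[4, 2] <- 11
  d[1, 4] <- d[4, 1] <- 12
  lab <- hierarchical_cluster(d, 2, "average")
  expect_identical(unname(lab), c(1L, 1L, 2L, 2L))
  expect_identical(unique(unname(hierarchical_cluster(d, 1))), 1L)
  expect_identical(sort(unname(hierarchical_cluster(d, 4))), 1:4)
  expect_error(hierarchical_cluster(d, 5), "exceeds")
})

test_that("select_k_connectivity finds three planted groups and reports a full trace", {
  set.seed(77)
  x <- cbind(rnorm(60, rep(c(0, 6, 12), each = 20), 0.5),
             rnorm(60, rep(c(0, 6, 12), each = 20), 0.5))
  dimnames(x) <- list(sprintf("s%02d", 1:60), c("f1", "f2"))
  d <- euclidean_distance(t(x))
  for (meth in c("kmeans", "hierarchical")) {
    sel <- select_k_connectivity(d, method = meth, opts = eval_options(seed = 2))
    expect_identical(sel$k, 3L)
    expect_identical(nrow(sel$trace), length(eval_options()$k_range))
    expect_equal(purity(sel$partition, stats::setNames(rep(1:3, each = 20), rownames(x))), 1)
  }
  # structureless data still returns a selection from the trace, no abstention
  set.seed(78)
  d0 <- euclidean_distance(matrix(rnorm(200), 10, 20,
                                  dimnames = list(paste0("g", 1:10), paste0("s", 1:20))))
  sel0 <- select_k_connectivity(d0, method = "kmeans", opts = eval_options(L = 5, seed = 3))
  expect_true(sel0$k %in% 2:5)
  conn <- sel0$trace$connectivity
  expect_equal(sel0$k, max(sel0$trace$k[conn <= min(conn) + 1e-9]))
})

test_that("select_k_connectivity is deterministic and reorder-invariant", {
  set.seed(88)
  x <- cbind(rnorm(30, rep(c(0, 5, 10), each = 10), 0.6), rnorm(30, 0, 0.6))
  dimnames(x) <- list(sprintf("s%02d", 1:30), c("f1", "f2"))
  d <- euclidean_distance(t(x))
  a <- select_k_connectivity(d, method = "kmeans", opts = eval_options(seed = 4))
  b <- select_k_connectivity(d, method = "kmeans", opts = eval_options(seed = 4))
  expect_identical(a$trace, b$trace)
  expect_identical(a$partition, b$partition)
  # permuting the samples permutes the partition but not its structure
  perm <- sample(rownames(d))
  dp <- d[perm, perm]
  sp <- select_k_connectivity(dp, method = "hierarchical", opts = eval_options())
  s0 <- select_k_connectivity(d, method = "hierarchical", opts = eval_options())
  expect_identical(sp$k, s0$k)
  expect_equal(purity(sp$partition[rownames(d)], s0$partition), 1)
  expect_equal(purity(s0$partition, sp$partition[rownames(d)]), 1)
})

test_that("evaluate_partition bundles the criteria into one row", {
  set.seed(5)
  d <- random_distance(8)
  lab <- stats::setNames(rep(1:2, each = 4), rownames(d))
  out <- evaluate_partition(lab, d, truth = lab, L = 3)
  expect_identical(nrow(out), 1L)
  expect_equal(out$purity, 1)
  expect_equal(out$connectivity, connectivity(lab, d, 3))
  expect_equal(out$dunn, dunn_index(lab, d))
})
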