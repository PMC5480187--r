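test_that("score formula matches the worked example", {
  # 4 pathways with m = (2,3,1,2); pair (s01, s02) co-clustered by pathway 1,
  # split by pathways 2 and 4; pathway 3 (m=1) does not vote -> 2/3
  cl <- list(
    fake_clustering("p1", c(1, 1, 2, 2)),
    fake_clustering("p2", c(1, 2, 3, 3)),
    fake_clustering("p3", c(1, 1, 1, 1)),
    fake_clustering("p4", c(2, 1, 1, 2))
  )
  s <- score_matrix(cl)
  expect_equal(attr(s, "n_voting_pathways"), 3L)
  expect_equal(s["s01", "s02"], 2 / 3)
  expect_equal(diag(unclass(s)), stats::setNames(rep(0, 4), rownames(s)))
})

test_that("unanimous partitions give 0 within and 1 across clusters", {
  lab <- c(1, 1, 2, 2, 3)
  cl <- lapply(1:5, function(i) fake_clustering(paste0("p", i), lab))
  s <- score_matrix(cl)
  same <- outer(lab, lab, `==`)
  expect_true(all(s[same] == 0))
  expect_true(all(s[!same] == 1))
})

test_that("score matrix equals the brute-force double loop on random partitions", {
  set.seed(202)
  for (rep in 1:5) {
    n <- 12
    K <- 20
    labs <- lapply(1:K, function(k) random_partition(n, sample(1:4, 1)))
    cl <- lapply(1:K, function(k) fake_clustering(paste0("p", k), labs[[k]]))
    ms <- vapply(cl, `[[`, integer(1), "m_k")
    s <- score_matrix(cl)
    named_labs <- lapply(cl, `[[`, "labels")
    expect_equal(unclass_keep(s), oracle_score_matrix(named_labs, ms),
                 tolerance = 1e-12)
    expect_equal(attr(s, "n_voting_pathways"), sum(ms > 1))
    # entries times the denominator are integer counts
    counts <- unclass_keep(s) * attr(s, "n_voting_pathways")
    expect_equal(counts, round(counts), tolerance = 1e-9)
  }
})

test_that("score matrix is invariant to pathway order, relabeling, and m=1 padding", {
  set.seed(7)
  labs <- lapply(1:6, function(k) random_partition(10, 3))
  cl <- lapply(1:6, function(k) fake_clustering(paste0("p", k), labs[[k]]))
  s <- score_matrix(cl)
  expect_equal(unclass_keep(score_matrix(rev(cl))), unclass_keep(s))
  # relabel cluster ids of one pathway
  relabeled <- cl
  relabeled[[2]]$labels[] <- as.integer(4 - relabeled[[2]]$labels)
  expect_equal(unclass_keep(score_matrix(relabeled)), unclass_keep(s))
  padded <- c(cl, list(fake_clustering("null", rep(1, 10))))
  expect_equal(unclass_keep(score_matrix(padded)), unclass_keep(s))
})

test_that("all-m1 collections raise the degenerate-score error carrying the zero matrix", {
  cl <- lapply(1:3, function(i) fake_clustering(paste0("p", i), rep(1, 5)))
  err <- expect_error(score_matrix(cl), class = "pathdist_degenerate_score")
  expect_true(all(err$score == 0))
  expect_identical(dim(err$score), c(5L, 5L))
})

test_that("final distance is the Euclidean distance between score columns", {
  s <- matrix(c(0, .5, 1, .5, 0, .5, 1, .5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  d <- final_distance(s)
  expect_equal(d["a", "c"], sqrt(2))
  # identical columns -> zero distance
  s2 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(final_distance(s2) == 0))
  # brute force on random valid score matrices + triangle inequality
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    labs <- lapply(1:8, function(k) random_partition(n, 3))
    cl <- lapply(1:8, function(k) fake_clustering(paste0("p", k), labs[[k]]))
    sm <- score_matrix(cl)
    fd <- final_distance(sm)
    expect_equal(fd, oracle_column_distance(unclass_keep(sm)), tolerance = 1e-12)
    for (i in 1:n) for (j in 1:n) for (l in 1:n) {
      expect_lte(fd[i, j], fd[i, l] + fd[l, j] + 1e-12)
    }
  }
})

test_that("euclidean comparator distances match brute force and de-duplicate genes", {
  m1 <- matrix(c(0, 3), 1, 2, dimnames = list("g1", c("a", "b")))
  expect_equal(euclidean_distance(m1)["a", "b"], 3)

  set.seed(9)
  m <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:8)))
  d <- euclidean_distance(m)
  expect_equal(d, oracle_column_distance(m), tolerance = 1e-12)

  # filter covering all genes is the identity; overlapping sets count genes once
  all_sets <- list(A = rownames(m)[1:20], B = rownames(m)[10:30])
  expect_equal(euclidean_distance(m, all_sets), d, tolerance = 1e-12)
  sub <- list(A = c("g01", "g02"), B = c("g02", "g03"))
  expect_equal(euclidean_distance(m, sub),
               oracle_column_distance(m[c("g01", "g02", "g03"), ]),
               tolerance = 1e-12)
  expect_error(euclidean_distance(m, list(A = "nope")), "no gene")
})

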