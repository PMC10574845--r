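test_that("mRMR demotes duplicated features below independent ones", {
  set.seed(42)
  n <- 500
  A <- runif(n)
  tab <- data.frame(fa = A, fb = A, fc = runif(n),
                    sbp = 50 * A + 100 + rnorm(n, 0, 2), dbp = runif(n, 60, 110))
  r <- mrmr_rank(tab, "sbp", k = 3)
  expect_identical(r$features[1], "fa")
  expect_identical(r$features, oracle_mrmr(tab, "sbp", 3))
})

test_that("greedy mRMR matches the brute-force oracle on random instances", {
  set.seed(7)
  for (trial in 1:4) {
    n <- sample(c(100, 400, 1000), 1)
    p <- sample(4:10, 1)
    X <- as.data.frame(matrix(runif(n * p), n))
    names(X) <- sprintf("f%02d", seq_len(p))
    X$sbp <- 100 + 30 * X$f01 + 10 * X$f02 * X$f03 + rnorm(n, 0, 3)
    X$dbp <- runif(n, 60, 110)
    k <- min(p, 6)
    expect_identical(mrmr_rank(X, "sbp", k = k)$features,
                     oracle_mrmr(X, "sbp", k),
                     info = paste("trial", trial))
  }
})

test_that("the first mRMR pick maximizes relevance alone", {
  set.seed(1)
  n <- 300
  tab <- data.frame(fa = runif(n), fb = runif(n))
  tab$sbp <- 120 + 20 * tab$fa + rnorm(n, 0, 1)
  tab$dbp <- runif(n, 60, 110)
  expect_identical(mrmr_rank(tab, "sbp", k = 1)$features, "fa")
})

test_that("rankers are invariant to row permutation", {
  set.seed(2)
  n <- 200
  tab <- data.frame(fa = runif(n), fb = runif(n), fc = runif(n))
  tab$sbp <- 110 + 25 * tab$fa + rnorm(n, 0, 2)
  tab$dbp <- runif(n, 60, 110)
  perm <- tab[sample(n), ]
  expect_identical(mrmr_rank(tab, "sbp", 3)$features,
                   mrmr_rank(perm, "sbp", 3)$features)
  r1 <- rrelieff_scores(tab, "sbp", n_iterations = n, seed = 1)
  r2 <- rrelieff_scores(perm, "sbp", n_iterations = n, seed = 1)
  expect_equal(r1$scores[sort(names(r1$scores))],
               r2$scores[sort(names(r2$scores))], tolerance = 1e-10)
})

test_that("mRMR clamps k and floors constant columns", {
  set.seed(3)
  tab <- data.frame(fa = runif(50), fconst = rep(1, 50))
  tab$sbp <- 100 + 10 * tab$fa + rnorm(50, 0.5)
  tab$dbp <- runif(50, 60, 110)
  expect_warning(r <- mrmr_rank(tab, "sbp", k = 10), "clamped")
  expect_identical(r$features[length(r$features)], "fconst")
  expect_true(is.infinite(r$scores[length(r$scores)]))
})

test_that("RReliefF matches the brute-force update on exhaustive neighbors", {
  set.seed(11)
  n <- 20
  X <- cbind(a = runif(n), b = runif(n), c = runif(n))
  y <- 100 + 30 * X[, "a"] + rnorm(n, 0, 1)
  tab <- data.frame(X, sbp = y, dbp = runif(n, 60, 110))
  r <- rrelieff_scores(tab, "sbp", n_neighbors = n - 1, n_iterations = n,
                       seed = 1)
  expected <- oracle_rrelieff(X, y, n_neighbors = n - 1)
  names(expected) <- colnames(X)
  expect_equal(r$scores[names(expected)], expected, tolerance = 1e-10)
})

test_that("RReliefF separates informative from noise features across seeds", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 500
    tab <- data.frame(fa = runif(n), fb = runif(n))
    tab$sbp <- 2 * tab$fa + rnorm(n, 0, 0.1)
    tab$dbp <- runif(n, 60, 110)
    r <- rrelieff_scores(tab, "sbp", seed = s)
    if (r$scores[["fa"]] > 0.001 && r$scores[["fb"]] < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("RReliefF is invariant to exact row duplication", {
  set.seed(5)
  n <- 150
  tab <- data.frame(fa = runif(n), fb = runif(n))
  tab$sbp <- 2 * tab$fa + rnorm(n, 0, 0.1)
  tab$dbp <- runif(n, 60, 110)
  r1 <- rrelieff_scores(tab, "sbp", n_iterations = n, seed = 1)
  r2 <- rrelieff_scores(tab[rep(seq_len(n), each = 2), ], "sbp",
                        n_iterations = 2 * n, seed = 1)
  expect_equal(r1$scores[sort(names(r1$scores))],
               r2$scores[sort(names(r2$scores))], tolerance = 1e-6)
})

test_that("degenerate all-identical rows score zero", {
  tab <- data.frame(fa = rep(1, 30), fb = rep(2, 30),
                    sbp = rep(120, 30), dbp = rep(80, 30))
  r <- rrelieff_scores(tab, "sbp", seed = 1)
  expect_true(all(r$scores == 0))
})

test_that("the significance threshold is a strict inequality", {
  rk <- structure(list(method = "rrelieff",
                       features = c("a", "b", "c", "d"),
                       scores = c(a = 0.1, b = 0.01, c = 0.001, d = 5e-4),
                       k_selected = 4L),
                  class = "ranking_result")
  expect_identical(choose_k(rk), 2L)
  rk$scores <- c(a = 1e-4, b = 1e-5, c = 0, d = -0.1)
  expect_warning(k <- choose_k(rk), "threshold")
  expect_identical(k, 0L)
})
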