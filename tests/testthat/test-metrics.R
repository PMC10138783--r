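test_that("confusion counts cover all L^2 cells", {
  truth <- matrix(0, 4, 4); truth[1, 4] <- truth[4, 1] <- 1
  perfect <- confusionCounts(truth, truth)
  expect_equal(perfect[["TP"]], 2L)
  expect_equal(perfect[["FP"]], 0L)
  expect_equal(perfect[["FN"]], 0L)
  expect_equal(perfect[["TN"]], 14L)
  blank <- confusionCounts(matrix(0, 4, 4), truth)
  expect_equal(blank[["FN"]], 2L)
  expect_equal(blank[["TN"]], 14L)
  zero <- confusionCounts(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_equal(zero[["TN"]], 16L)
  expect_error(confusionCounts(matrix(0, 3, 3), truth), "shape")
})

test_that("the two printed F1 forms agree over random confusion counts", {
  set.seed(17)
  for (i in 1:2000) {
    L <- sample(2:50, 1)
    cells <- L^2
    cut <- sort(sample(0:cells, 3, replace = TRUE))
    cc <- c(TP = cut[1], FP = cut[2] - cut[1], FN = cut[3] - cut[2],
            TN = cells - cut[3], L = L)
    f1a <- f1Score(cc)
    den <- cells + cc[["TP"]] - cc[["TN"]]
    f1b <- if (den == 0) 0 else 2 * cc[["TP"]] / den
    expect_equal(f1a, f1b)
  }
})

test_that("f1Score handles edge values and pred/truth swaps", {
  expect_equal(f1Score(c(TP = 2, FP = 0, FN = 0)), 1.0)
  expect_equal(f1Score(c(TP = 0, FP = 5, FN = 3)), 0.0)
  expect_equal(f1Score(c(TP = 0, FP = 0, FN = 0)), 0)
  expect_equal(f1Score(c(TP = 3, FP = 1, FN = 2)), 6 / 9)
  # swapping prediction and truth swaps FP and FN, leaving F1 unchanged
  expect_equal(f1Score(c(TP = 3, FP = 2, FN = 1)),
               f1Score(c(TP = 3, FP = 1, FN = 2)))
})

test_that("upper-triangle accounting changes TN but not F1", {
  set.seed(3)
  truth <- matrix(0, 8, 8)
  truth[2, 7] <- truth[7, 2] <- 1
  pred <- matrix(0, 8, 8)
  pred[2, 7] <- pred[7, 2] <- 1; pred[1, 5] <- pred[5, 1] <- 1
  full <- confusionCounts(pred, truth)
  ut <- confusionCounts(pred, truth, upperTriangleOnly = TRUE)
  expect_equal(f1Score(full), f1Score(ut))
  expect_gt(full[["TN"]], ut[["TN"]])
})

test_that("ensemble F1 weights every sequence equally", {
  expect_equal(ensembleF1(c(1, 0)), 0.5)
  expect_equal(ensembleF1(0.7), 0.7)
  expect_error(ensembleF1(numeric(0)), "empty")
  # unbalanced toy: sequence mean differs from family mean-of-means
  f1s <- c(famA = 1.0, famA = 1.0, famB = 0.0)
  expect_equal(ensembleF1(f1s), 2 / 3)
  famMeans <- tapply(f1s, names(f1s), mean)
  expect_equal(mean(famMeans), 0.5)   # not what ensembleF1 computes
})

test_that("pgScore matches its formula, clips G at 1, and is bounded", {
  r <- pgScore(0.9, 0.9)
  expect_equal(r$G, 1.0)
  expect_equal(r$pgscore, 2 * 0.9 / 1.9)
  r2 <- pgScore(0.903, 0.665)
  expect_equal(r2$G, 0.665 / 0.903)
  expect_equal(r2$pgscore, 2 * 0.903 * r2$G / (0.903 + r2$G),
               tolerance = 1e-12)
  expect_equal(r2$pgscore, 0.8112, tolerance = 2e-4)
  expect_equal(pgScore(0.5, 0)$pgscore, 0)
  expect_error(pgScore(0, 0.5), "positive")
  # harmonic mean is below arithmetic mean and max when P != G
  set.seed(5)
  for (i in 1:50) {
    P <- runif(1, 0.05, 1); ts <- runif(1, 0, P)
    r <- pgScore(P, ts)
    expect_lte(r$pgscore, (r$P + r$G) / 2 + 1e-12)
    expect_lte(r$pgscore, max(r$P, r$G) + 1e-12)
  }
  expect_equal(pgScore(0.7, 0.7)$pgscore,
               pgScore(0.7, 0.7)$P * 2 * 1 / (0.7 + 1))
})

test_that("KS comparison matches the brute-force ECDF statistic", {
  expect_lt(ksCompare(1:10 / 10, 1:10 / 10)$statistic, 1e-12)
  expect_gt(ksCompare(1:10 / 10, 1:10 / 10)$p_value, 0.99)
  lo <- seq(0, 0.1, length.out = 10); hi <- seq(0.9, 1, length.out = 10)
  expect_equal(ksCompare(lo, hi)$statistic, 1.0)
  set.seed(29)
  for (i in 1:10) {
    a <- runif(20); b <- rbeta(20, 2, 1)
    expect_equal(ksCompare(a, b)$statistic, bruteKS(a, b))
  }
  expect_error(ksCompare(1, 1:5), "at least 2")
})

test_that("soft-F1 variance is zero for binary PPMs and matches hand algebra", {
  truth <- matrix(0, 5, 5); truth[1, 5] <- truth[5, 1] <- 1
  expect_equal(softF1Variance(truth, truth), 0)
  expect_equal(softF1Variance(1 - truth, truth), 0)
  # single-cell toy at p = 0.5, y = 1: F is 0 or 1 with probability 1/2,
  # so the exact variance is 1/4; the delta method propagates the cell
  # variance 0.25 through the analytic partial instead
  p <- matrix(0.5, 1, 1); y <- matrix(1, 1, 1)
  expect_equal(softF1Variance(p, y), 0.25, tolerance = 1e-9)
  A <- 0.5; D <- 1.5 + 1e-12
  dF <- 2 * (1 * D - A) / D^2
  expect_equal(softF1Variance(p, y, method = "delta"), dF^2 * 0.25)
})

test_that("soft-F1 variance agrees with Monte-Carlo simulation", {
  set.seed(31)
  for (rep in 1:3) {
    p <- matrix(runif(36, 0.05, 0.95), 6, 6)
    y <- matrix(rbinom(36, 1, 0.25), 6, 6)
    if (sum(y) == 0) y[2, 5] <- 1
    est <- softF1Variance(p, y)
    nmc <- 1e5
    draws <- matrix(rbinom(36 * nmc, 1, rep(as.vector(p), nmc)), nrow = 36)
    f1mc <- apply(draws, 2, function(d) {
      tp <- sum(d * as.vector(y))
      2 * tp / (sum(d) + sum(y) + 1e-12)
    })
    vmc <- stats::var(f1mc)
    m4 <- mean((f1mc - mean(f1mc))^4)
    se <- sqrt((m4 - vmc^2) / nmc) + 1e-10  # SE of the sample variance
    expect_lt(abs(est - vmc), 3 * se)
  }
})

test_that("delta-method variance approaches the exact value for large matrices", {
  set.seed(8)
  L <- 40
  p <- matrix(runif(L^2, 0.01, 0.2), L, L)
  y <- matrix(0, L, L)
  idx <- sample(L^2, 2 * L)
  y[idx] <- 1
  p[idx] <- runif(2 * L, 0.5, 0.99)
  ex <- softF1Variance(p, y, method = "exact")
  de <- softF1Variance(p, y, method = "delta")
  expect_lt(abs(de - ex) / ex, 0.1)
})
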