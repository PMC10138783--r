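#' @include AllClasses.R
NULL

#' Element-wise confusion counts between two binary pairing matrices
#'
#' All `L^2` cells (both triangles and the diagonal) are counted, with no
#' allowance for base pairs displaced by one nucleotide.
#'
#' @param pred,truth symmetric binary matrices of equal shape.
#' @param upperTriangleOnly count only the strict upper triangle. The F1
#'   score is unchanged for symmetric inputs; only TN (and the total)
#'   differ.
#' @return named integer vector `TP`, `FP`, `FN`, `TN`, `L` with
#'   `TP + FP + FN + TN = L^2` (full-matrix accounting).
#' @export
confusionCounts <- function(pred, truth, upperTriangleOnly = FALSE) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  L <- nrow(pred)
  if (upperTriangleOnly) {
    keep <- upper.tri(pred)
    pred <- pred[keep]; truth <- truth[keep]
  }
  p <- pred != 0; y <- truth != 0
  c(TP = sum(p & y), FP = sum(p & !y), FN = sum(!p & y), TN = sum(!p & !y),
    L = L)
}

#' F1 score from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`, defined as 0 when the denominator vanishes.
#' Algebraically identical to `2 TP / (L^2 + TP - TN)` under full-matrix
#' accounting.
#'
#' @param counts named vector with `TP`, `FP`, `FN` (as from
#'   [confusionCounts()]).
#' @return scalar in `[0, 1]`.
#' @export
f1Score <- function(counts) {
  den <- 2 * counts[["TP"]] + counts[["FP"]] + counts[["FN"]]
  if (den == 0) return(0)
  2 * counts[["TP"]] / den
}

#' Ensemble mean F1
#'
#' The unweighted mean over per-sequence F1 scores: every sequence counts
#' equally, rather than averaging family means.
#'
#' @param f1s non-empty numeric vector of per-record F1 scores.
#' @return scalar mean.
#' @export
ensembleF1 <- function(f1s) {
  if (length(f1s) == 0) stop("empty F1 vector")
  mean(f1s)
}

#' Performance-generalizability score
#'
#' `PGscore = 2 P G / (P + G)` where `P` is the training-set mean F1 and
#' `G = min(TS/TR, 1)` the test-to-train ratio (values above 1 are
#' clipped).
#'
#' @param trMeanF1 training mean F1 in (0, 1].
#' @param tsMeanF1 test mean F1, non-negative.
#' @return list with elements `P`, `G` and `pgscore`.
#' @export
pgScore <- function(trMeanF1, tsMeanF1) {
  if (trMeanF1 <= 0) stop("training mean F1 must be positive")
  P <- trMeanF1
  G <- min(tsMeanF1 / trMeanF1, 1)
  pg <- if (P + G > 0) 2 * P * G / (P + G) else 0
  list(P = P, G = G, pgscore = pg)
}

#' Two-sample Kolmogorov-Smirnov comparison of F1 distributions
#'
#' Two-sided statistic with asymptotic p-value.
#'
#' @param f1sA,f1sB numeric samples with at least 2 values each.
#' @return list with `statistic` and `p_value`.
#' @export
ksCompare <- function(f1sA, f1sB) {
  if (length(f1sA) < 2 || length(f1sB) < 2)
    stop("both samples need at least 2 values")
  kt <- suppressWarnings(stats::ks.test(f1sA, f1sB, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Variance of the soft F1 score under per-cell pairing uncertainty
#'
#' Each predicted probability is treated as an independent two-state
#' variable with variance `p (1 - p)`. The soft F1 score
#' `F = 2 A / (A + B + n1)` depends on the cells only through the sum `A`
#' over positive-label cells and the sum `B` over negative-label cells
#' (`n1 = sum(y)`), each a Poisson-binomial variable whose distribution is
#' computed exactly by convolution, so the default (`method = "exact"`,
#' used up to 4096 cells) returns the exact variance. For larger matrices
#' the delta method is used: gradient propagation through
#' `dF/dp_ij = 2 (y_ij D - A) / D^2` with `D = sum(p) + sum(y)`
#' (`method = "delta"`), which is accurate there because the relative
#' fluctuation of `D` shrinks with the number of cells.
#'
#' @param ppm predicted probability matrix.
#' @param truth binary reference matrix of the same shape.
#' @param method `"auto"` (exact up to 4096 cells, delta beyond),
#'   `"exact"`, or `"delta"`.
#' @return scalar variance estimate (0 for a binary PPM).
#' @export
softF1Variance <- function(ppm, truth, method = c("auto", "exact", "delta")) {
  method <- match.arg(method)
  stopifnot(all(dim(ppm) == dim(truth)))
  p <- as.vector(ppm); y <- as.vector(truth)
  if (method == "auto") method <- if (length(p) <= 4096) "exact" else "delta"
  if (method == "exact") {
    pmfA <- poissonBinomialPmf(p[y != 0])
    pmfB <- poissonBinomialPmf(p[y == 0])
    n1 <- sum(y != 0)
    a <- seq_along(pmfA) - 1  # support of A
    b <- seq_along(pmfB) - 1
    Fab <- outer(a, b, function(s, t) 2 * s / (s + t + n1 + 1e-12))
    w <- outer(pmfA, pmfB)
    m1 <- sum(w * Fab)
    m2 <- sum(w * Fab^2)
    return(max(m2 - m1^2, 0))
  }
  v <- p * (1 - p)
  A <- sum(p * y)
  D <- sum(p) + sum(y) + 1e-12
  g <- 2 * (y * D - A) / D^2
  sum(g^2 * v)
}

# exact PMF of a sum of independent Bernoulli(p_i) variables
poissonBinomialPmf <- function(probs) {
  f <- 1
  for (q in probs) f <- c(f * (1 - q), 0) + c(0, f * q)
  f
}

#' Write per-record metrics as TSV and ensemble summaries as JSON
#'
#' @param perRecord data frame from [evaluateModel()].
#' @param tsvPath,jsonPath output paths (either may be `NULL`).
#' @return the ensemble summary list, invisibly.
#' @export
writeMetrics <- function(perRecord, tsvPath = NULL, jsonPath = NULL) {
  summary <- list(n = nrow(perRecord), mean_f1 = ensembleF1(perRecord$f1))
  if (!is.null(tsvPath))
    utils::write.table(perRecord, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
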