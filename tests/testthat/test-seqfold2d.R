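test_that("input encoding windows, pads and averages ambiguity codes", {
  eA <- encodeInput("A")
  expect_equal(dim(eA), c(1L, 12L))
  expect_equal(eA[1, ], c(rep(0, 4), 1, 0, 0, 0, rep(0, 4)))
  eAC <- encodeInput("AC")
  expect_equal(eAC[1, ], c(0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0))
  expect_equal(eAC[2, ], c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0))
  eN <- encodeInput("N")
  expect_equal(eN[1, 5:8], rep(0.25, 4))
  eR <- encodeInput("R")        # A or G
  expect_equal(eR[1, 5:8], c(0.5, 0, 0.5, 0))
  expect_error(encodeInput(""), "empty")
  expect_equal(dim(encodeInput("ACGUACG", k = 5L)), c(7L, 20L))
})

test_that("parameter counts land on the published model sizes", {
  small <- countParams(ModelConfig(N = 1L, C = 16L))
  big <- countParams(ModelConfig(N = 4L, C = 64L))
  expect_equal(signif(small, 2), 16000)
  expect_equal(signif(big, 2), 960000)
  expect_gt(countParams(ModelConfig(N = 2L, C = 16L)),
            countParams(ModelConfig(N = 1L, C = 16L)))
  expect_gt(countParams(ModelConfig(N = 1L, C = 32L)),
            countParams(ModelConfig(N = 1L, C = 16L)))
})

test_that("forward output is a symmetric probability matrix; untrained = 0.5", {
  mod <- seqFold2D(ModelConfig(N = 2L, C = 6L), seed = 4L)
  s <- "GGGCAAAAGCCC"
  ppm <- predictPPM(mod, s)
  expect_equal(dim(ppm), c(12L, 12L))
  expect_true(all(ppm >= 0 & ppm <= 1))
  expect_lt(max(abs(ppm - t(ppm))), 1e-6)
  expect_true(all(ppm == 0.5))   # zero-initialised head
  expect_identical(predictPPM(mod, s), predictPPM(mod, s))  # eval determinism
  expect_error(predictPPM(mod, paste(rep("A", 601), collapse = "")),
               "exceeds")
})

test_that("losses reproduce their closed forms", {
  y <- matrix(0, 4, 4); y[1, 4] <- y[4, 1] <- 1
  expect_lt(ceLoss(y, y), 1e-6)
  expect_equal(ceLoss(matrix(0.5, 4, 4), y), log(2))
  # single cell y = 1 predicted at 0.25 contributes -log(0.25)
  p <- y; p[1, 4] <- 0.25
  expect_equal(ceLoss(p, y), -log(0.25) / 16, tolerance = 1e-5)

  expect_equal(softF1Loss(y, y), 0, tolerance = 1e-9)
  expect_equal(softF1Loss(1 - y, y), 1, tolerance = 1e-9)
  m <- sum(y); n <- length(y)
  expect_equal(softF1Loss(matrix(0.5, 4, 4), y),
               1 - 2 * (0.5 * m) / (m + 0.5 * n), tolerance = 1e-9)
})

test_that("binarization uses a >= threshold", {
  half <- matrix(0.5, 3, 3)
  expect_true(all(binarizePPM(half) == 1))
  expect_true(all(binarizePPM(matrix(0, 3, 3)) == 0))
  expect_true(all(binarizePPM(half, 1.1) == 0))
})

test_that("analytic gradients match finite differences for both losses", {
  cfg <- ModelConfig(N = 2L, C = 4L, dropout = 0)
  clist <- ppmfold:::cfgList(cfg)
  s <- "GGGCAAAAGCCCAU"
  X <- encodeInput(s)
  Y <- pairsToMatrix(RnaRecordSet("a", s, pairs = list(nussinovFold(s))))
  for (lossType in c(0L, 1L)) {
    set.seed(100 + lossType)
    P <- seqFold2D(cfg, seed = 20L + lossType)@params
    out <- ppmfold:::.sf2d_run_cpp(P, X, Y, clist, FALSE, lossType, TRUE)
    for (nm in names(P)) {
      g <- out$grads[[nm]]
      for (i in sample(length(P[[nm]]), min(4, length(P[[nm]])))) {
        eps <- 1e-5
        Pp <- P; Pp[[nm]][i] <- Pp[[nm]][i] + eps
        Pm <- P; Pm[[nm]][i] <- Pm[[nm]][i] - eps
        fd <- (ppmfold:::.sf2d_run_cpp(Pp, X, Y, clist, FALSE, lossType,
                                       FALSE)$loss -
               ppmfold:::.sf2d_run_cpp(Pm, X, Y, clist, FALSE, lossType,
                                       FALSE)$loss) / (2 * eps)
        rel <- abs(fd - g[i]) / max(abs(fd), abs(g[i]), 1e-8)
        expect_lt(rel, 1e-4)
      }
    }
  }
})

test_that("soft-F1 partial derivatives match finite differences on random PPMs", {
  set.seed(77)
  p <- matrix(runif(36, 0.05, 0.95), 6, 6)
  y <- matrix(rbinom(36, 1, 0.3), 6, 6)
  A <- sum(p * y); D <- sum(p) + sum(y) + 1e-12
  analytic <- -2 * (y * D - A) / D^2    # d(loss)/dp
  eps <- 1e-6
  for (idx in sample(36, 8)) {
    pp <- p; pp[idx] <- pp[idx] + eps
    pm <- p; pm[idx] <- pm[idx] - eps
    fd <- (softF1Loss(pp, y) - softF1Loss(pm, y)) / (2 * eps)
    expect_equal(analytic[idx], fd, tolerance = 1e-4)
  }
})

test_that("training follows the two-stage schedule and early-stop contract", {
  corp <- tinyCorpus(24L, seed = 55L)
  mc <- ModelConfig(N = 1L, C = 6L, dropout = 0.1)
  sch <- TrainSchedule(learningRate = 3e-3, batchSize = 4L, maxEpochs = 12L,
                       plateauPatience = 2L, earlyStopPatience = 4L,
                       seed = 9L)
  mod <- seqFold2D(mc, seed = 9L)
  fit <- trainModel(mod, corp[1:18], corp[19:24], sch)
  h <- fit@history
  expect_true(all(c("epoch", "stage", "tr_loss", "vl_loss", "tr_f1",
                    "vl_f1") %in% names(h)))
  expect_true(all(diff(h$stage) >= 0))           # stages never revert
  # identical seed reproduces the identical history
  fit2 <- trainModel(seqFold2D(mc, seed = 9L), corp[1:18], corp[19:24], sch)
  expect_identical(fit@history, fit2@history)
  # returned parameters are the best-VL-F1 parameters, never a later epoch
  cfg <- ppmfold:::cfgList(mc)
  enc <- lapply(rnaSequences(corp[19:24]), encodeInput)
  Y <- lapply(1:6, function(i) pairsToMatrix(corp[19:24], i))
  vlF1 <- ppmfold:::evalMeanF1(fit@params, cfg, enc, Y)
  expect_equal(vlF1, max(h$vl_f1))
})

test_that("an overparameterized net memorizes a small corpus", {
  corp <- generateCorpus(CorpusConfig(
    nRecords = 50L, nFamilies = 2L, familyShares = c(0.6, 0.4),
    lengthRanges = cbind(c(18, 20), c(26, 28)),
    intraMutationRate = 0.1, clusterRedundancy = 1, seed = 7L))
  mc <- ModelConfig(N = 1L, C = 16L, dropout = 0.2)
  sch <- TrainSchedule(learningRate = 5e-3, batchSize = 4L, maxEpochs = 200L,
                       plateauPatience = 2L, earlyStopPatience = 60L,
                       seed = 3L)
  mod <- trainModel(seqFold2D(mc, seed = 3L), corp[1:40], corp[41:50], sch)
  trF1 <- mean(evaluateModel(mod, corp[1:40])$f1)
  expect_gte(trF1, 0.8)
})

test_that("the swish activation variant forwards and differentiates correctly", {
  cfg <- ModelConfig(N = 1L, C = 4L, dropout = 0, activation = "swish")
  clist <- ppmfold:::cfgList(cfg)
  s <- "GGGCAAAAGCCC"
  X <- encodeInput(s)
  Y <- pairsToMatrix(RnaRecordSet("a", s, pairs = list(nussinovFold(s))))
  mod <- seqFold2D(cfg, seed = 6L)
  ppm <- predictPPM(mod, s)
  expect_true(all(ppm >= 0 & ppm <= 1))
  set.seed(8)
  P <- mod@params
  out <- ppmfold:::.sf2d_run_cpp(P, X, Y, clist, FALSE, 0L, TRUE)
  for (nm in sample(names(P), 6)) {
    i <- sample(length(P[[nm]]), 1)
    eps <- 1e-5
    Pp <- P; Pp[[nm]][i] <- Pp[[nm]][i] + eps
    Pm <- P; Pm[[nm]][i] <- Pm[[nm]][i] - eps
    fd <- (ppmfold:::.sf2d_run_cpp(Pp, X, Y, clist, FALSE, 0L, FALSE)$loss -
           ppmfold:::.sf2d_run_cpp(Pm, X, Y, clist, FALSE, 0L, FALSE)$loss) /
      (2 * eps)
    expect_lt(abs(fd - out$grads[[nm]][i]) /
                max(abs(fd), abs(out$grads[[nm]][i]), 1e-8), 1e-4)
  }
})

test_that("training schedules round trip through YAML", {
  sch <- TrainSchedule(learningRate = 2e-3, batchSize = 8L, seed = 42L)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeTrainSchedule(sch, f)
  back <- readTrainSchedule(f)
  expect_equal(back@learningRate, sch@learningRate)
  expect_equal(back@batchSize, sch@batchSize)
  expect_equal(back@seed, sch@seed)
  expect_equal(back@clipNorm, sch@clipNorm)
})
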