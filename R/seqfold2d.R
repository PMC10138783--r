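#' @include AllClasses.R AllGenerics.R curation.R
NULL

# width conventions: these fix the architecture's free widths and hence
# the parameter count reported by countParams()
hiddenWidth <- function(C) as.integer(round(1.25 * C))
convMidWidth <- function(C) as.integer(round(1.75 * C))

#' One-hot k-mer input encoding
#'
#' Each position is encoded as the concatenation of the one-hot vectors of
#' the `k` positions centred on it (zero vectors beyond the sequence
#' ends), giving an `L x 4k` matrix. IUPAC ambiguity codes are encoded as
#' the mean of their compatible one-hots (`N` becomes 1/4 everywhere).
#'
#' @param sequence RNA sequence.
#' @param k window size (odd).
#' @return numeric matrix of dimension `L x 4k`.
#' @export
encodeInput <- function(sequence, k = 3L) {
  if (nchar(sequence) == 0) stop("empty sequence")
  if (k %% 2 == 0) stop("k must be odd")
  b <- strsplit(toupper(chartr("Tt", "Uu", sequence)), "")[[1]]
  L <- length(b)
  onehot <- matrix(0, L, 4)
  for (i in seq_len(L)) {
    comp <- IUPAC_RNA[[b[i]]]
    if (is.null(comp)) stop("unknown nucleotide code: ", b[i])
    onehot[i, match(comp, RNA_BASES)] <- 1 / length(comp)
  }
  half <- (k - 1L) %/% 2L
  out <- matrix(0, L, 4L * k)
  for (w in seq_len(k)) {
    off <- w - 1L - half
    src <- seq_len(L) + off
    ok <- src >= 1L & src <= L
    out[ok, (w - 1L) * 4L + 1:4] <- onehot[src[ok], , drop = FALSE]
  }
  out
}

xavier <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

initParams <- function(config, seed = 1L) {
  C <- config@C; N <- config@N
  Fdim <- 4L * config@k
  h <- hiddenWidth(C); Cm <- convMidWidth(C)
  withSeed(seed, {
    P <- list(
      inp_W0 = xavier(Fdim, C), inp_b0 = numeric(C),
      inp_W1 = xavier(C, C), inp_b1 = numeric(C))
    for (n in seq_len(N)) {
      p <- sprintf("s%d_", n)
      fb <- numeric(4 * h); fb[(h + 1):(2 * h)] <- 1  # forget bias 1
      P[[paste0(p, "ln_g")]] <- rep(1, C)
      P[[paste0(p, "ln_b")]] <- numeric(C)
      P[[paste0(p, "Wxf")]] <- xavier(C, 4 * h)
      P[[paste0(p, "Whf")]] <- xavier(h, 4 * h)
      P[[paste0(p, "bf")]] <- fb
      P[[paste0(p, "Wxb")]] <- xavier(C, 4 * h)
      P[[paste0(p, "Whb")]] <- xavier(h, 4 * h)
      P[[paste0(p, "bb")]] <- fb
      P[[paste0(p, "Wp")]] <- xavier(2 * h, C)
      P[[paste0(p, "bp")]] <- numeric(C)
      P[[paste0(p, "Wq")]] <- xavier(C, C)
      P[[paste0(p, "bq")]] <- numeric(C)
    }
    for (n in seq_len(N)) {
      p <- sprintf("c%d_", n)
      P[[paste0(p, "n1_g")]] <- rep(1, C)
      P[[paste0(p, "n1_b")]] <- numeric(C)
      P[[paste0(p, "K1")]] <- xavier(9 * C, Cm) / 3  # 3x3 fan-in
      P[[paste0(p, "cb1")]] <- numeric(Cm)
      P[[paste0(p, "n2_g")]] <- rep(1, Cm)
      P[[paste0(p, "n2_b")]] <- numeric(Cm)
      P[[paste0(p, "K2")]] <- xavier(9 * Cm, C) / 3
      P[[paste0(p, "cb2")]] <- numeric(C)
    }
    P$head_W1 <- xavier(C, C); P$head_b1 <- numeric(C)
    P$head_W2 <- xavier(C, C); P$head_b2 <- numeric(C)
    # zero-initialised output layer: the untrained net predicts 0.5 everywhere
    P$head_W3 <- matrix(0, C, 2); P$head_b3 <- numeric(2)
    P
  })
}

#' Construct an untrained model
#'
#' @param config a [ModelConfig-class].
#' @param seed seed for weight initialisation.
#' @return a [SeqFold2DModel-class].
#' @export
seqFold2D <- function(config = ModelConfig(), seed = 1L) {
  new("SeqFold2DModel", config = config, params = initParams(config, seed),
      history = data.frame())
}

#' Count trainable parameters of a configuration
#'
#' Under the package's width conventions (bidirectional LSTM hidden width
#' `round(1.25 C)` per direction with `2h -> C` projection plus a `C -> C`
#' feed-forward per sequence block; convolution channels
#' `C -> round(1.75 C) -> C`; head `C -> C -> C -> 2`), `N = 1, C = 16`
#' gives about 16K parameters and `N = 4, C = 64` about 960K.
#'
#' @param config a [ModelConfig-class].
#' @return integer scalar count of trainable values.
#' @export
countParams <- function(config) {
  sum(vapply(initParams(config, seed = 1L), length, 1L))
}

cfgList <- function(config) {
  list(N = config@N, act = match(config@activation, c("leakyrelu", "swish")) - 1L,
       dropout = config@dropout)
}

#' Predict the pairing probability matrix for one sequence
#'
#' Deterministic (dropout off). The raw softmax output is symmetrised as
#' `(M + t(M)) / 2`.
#'
#' @param model a [SeqFold2DModel-class].
#' @param sequence RNA sequence of length at most `config@maxLen`.
#' @return `L x L` matrix of pairing probabilities in `[0, 1]`.
#' @export
predictPPM <- function(model, sequence) {
  if (nchar(sequence) > model@config@maxLen)
    stop(sprintf("sequence length %d exceeds maximum %d", nchar(sequence),
                 model@config@maxLen))
  X <- encodeInput(sequence, model@config@k)
  out <- .sf2d_run_cpp(model@params, X, matrix(0, 0, 0), cfgList(model@config),
                       FALSE, -1L, FALSE)
  out$ppm
}

#' Binarize a pairing probability matrix
#'
#' @param ppm probability matrix.
#' @param threshold entries at or above this become 1 (default 0.5).
#' @return binary matrix of the same shape.
#' @export
binarizePPM <- function(ppm, threshold = 0.5) {
  (ppm >= threshold) * 1
}

#' Equal-weight binary cross-entropy loss
#'
#' Mean over unmasked cells of `-(y log p + (1 - y) log(1 - p))` with
#' probabilities clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param ppm predicted probability matrix.
#' @param truth binary reference matrix of the same shape.
#' @param mask optional logical/binary matrix; `0` cells are excluded.
#' @return scalar loss.
#' @export
ceLoss <- function(ppm, truth, mask = NULL) {
  stopifnot(all(dim(ppm) == dim(truth)))
  p <- pmin(pmax(ppm, 1e-7), 1 - 1e-7)
  cell <- -(truth * log(p) + (1 - truth) * log(1 - p))
  if (is.null(mask)) mean(cell) else sum(cell[mask != 0]) / sum(mask != 0)
}

#' Differentiable soft F1 loss
#'
#' `1 - 2 TPs / (2 TPs + FPs + FNs + eps)` with soft counts
#' `TPs = sum(p y)`, `FPs = sum(p (1 - y))`, `FNs = sum((1 - p) y)` over
#' unmasked cells, `eps = 1e-12`.
#'
#' @inheritParams ceLoss
#' @return scalar loss in `[0, 1]`.
#' @export
softF1Loss <- function(ppm, truth, mask = NULL) {
  stopifnot(all(dim(ppm) == dim(truth)))
  if (!is.null(mask)) {
    keep <- mask != 0
    p <- ppm[keep]; y <- truth[keep]
  } else { p <- ppm; y <- truth }
  tp <- sum(p * y); fp <- sum(p * (1 - y)); fn <- sum((1 - p) * y)
  1 - 2 * tp / (2 * tp + fp + fn + 1e-12)
}

# mean F1 over a list of encoded records, forward pass only
evalMeanF1 <- function(params, cfg, enc, truth, idx = seq_along(enc)) {
  f1 <- vapply(idx, function(i) {
    out <- .sf2d_run_cpp(params, enc[[i]], matrix(0, 0, 0), cfg, FALSE, -1L,
                         FALSE)
    f1Score(confusionCounts(binarizePPM(out$ppm), truth[[i]]))
  }, 1)
  mean(f1)
}

#' Train a model with the two-stage schedule
#'
#' Stage 1 minimises equal-weight binary cross-entropy with AdamW; once
#' the validation CE has failed to improve by `relTol` (relative) for
#' `plateauPatience` consecutive epochs, stage 2 minimises the soft-F1
#' loss and training stops when the validation mean F1 has not improved
#' for `earlyStopPatience` epochs (or at `maxEpochs`). The returned model
#' carries the parameters of the best-validation-F1 epoch and a history
#' data frame (epoch, stage, tr_loss, vl_loss, tr_f1, vl_f1).
#'
#' @param model an untrained or pre-trained [SeqFold2DModel-class].
#' @param trRecords,vlRecords non-empty [RnaRecordSet-class] objects.
#' @param schedule a [TrainSchedule-class].
#' @param verbose print per-epoch progress.
#' @return the trained [SeqFold2DModel-class].
#' @export
trainModel <- function(model, trRecords, vlRecords,
                       schedule = TrainSchedule(), verbose = FALSE) {
  stopifnot(length(trRecords) > 0, length(vlRecords) > 0)
  config <- model@config
  cfg <- cfgList(config)
  encode <- function(recs) lapply(recs@sequence, encodeInput, k = config@k)
  truthOf <- function(recs) lapply(seq_along(recs@id),
                                   function(i) pairsToMatrix(recs, i))
  trEnc <- encode(trRecords); trY <- truthOf(trRecords)
  vlEnc <- encode(vlRecords); vlY <- truthOf(vlRecords)

  P <- model@params
  mState <- lapply(P, function(p) p * 0)
  vState <- lapply(P, function(p) p * 0)
  step <- 0L
  lr <- schedule@learningRate; wd <- schedule@weightDecay
  b1 <- 0.9; b2 <- 0.999; adamEps <- 1e-8
  nTr <- length(trEnc)

  history <- list()
  stage <- 1L
  bestVlCe <- Inf; ceStall <- 0L
  bestVlF1 <- -Inf; f1Stall <- 0L
  bestParams <- P

  trEvalIdx <- seq_len(min(nTr, schedule@evalCap))
  vlEvalIdx <- seq_len(min(length(vlEnc), schedule@evalCap))

  withSeed(schedule@seed, {
    for (epoch in seq_len(schedule@maxEpochs)) {
      ord <- sample.int(nTr)
      lossType <- stage - 1L  # 0 = CE, 1 = soft F1
      epochLoss <- 0
      bstart <- seq(1L, nTr, by = schedule@batchSize)
      for (bs in bstart) {
        batch <- ord[bs:min(bs + schedule@batchSize - 1L, nTr)]
        gAcc <- NULL
        for (i in batch) {
          out <- .sf2d_run_cpp(P, trEnc[[i]], trY[[i]], cfg, TRUE, lossType,
                               TRUE)
          if (!is.finite(out$loss))
            stop(sprintf("training diverged (loss = %s) at epoch %d",
                         out$loss, epoch))
          epochLoss <- epochLoss + out$loss
          g <- out$grads
          gAcc <- if (is.null(gAcc)) g
                  else mapply(`+`, gAcc, g[names(gAcc)], SIMPLIFY = FALSE)
        }
        scale <- 1 / length(batch)
        gnorm <- sqrt(sum(vapply(gAcc, function(g) sum((g * scale)^2), 1)))
        if (gnorm > schedule@clipNorm) scale <- scale * schedule@clipNorm / gnorm
        lrEff <- if (stage == 2L) lr * schedule@stage2LrFactor else lr
        step <- step + 1L
        bc1 <- 1 - b1^step; bc2 <- 1 - b2^step
        for (nm in names(P)) {
          g <- gAcc[[nm]] * scale
          mState[[nm]] <- b1 * mState[[nm]] + (1 - b1) * g
          vState[[nm]] <- b2 * vState[[nm]] + (1 - b2) * g * g
          P[[nm]] <- P[[nm]] - lrEff * ((mState[[nm]] / bc1) /
                     (sqrt(vState[[nm]] / bc2) + adamEps) + wd * P[[nm]])
        }
      }
      # epoch-end validation
      vlCe <- mean(vapply(vlEvalIdx, function(i) {
        out <- .sf2d_run_cpp(P, vlEnc[[i]], vlY[[i]], cfg, FALSE, 0L, FALSE)
        out$loss
      }, 1))
      vlF1 <- evalMeanF1(P, cfg, vlEnc, vlY, vlEvalIdx)
      trF1 <- evalMeanF1(P, cfg, trEnc, trY, trEvalIdx)
      history[[epoch]] <- data.frame(epoch = epoch, stage = stage,
                                     tr_loss = epochLoss / nTr,
                                     vl_loss = vlCe, tr_f1 = trF1,
                                     vl_f1 = vlF1)
      if (verbose)
        message(sprintf("epoch %3d stage %d tr_loss %.4f vl_ce %.4f tr_f1 %.3f vl_f1 %.3f",
                        epoch, stage, epochLoss / nTr, vlCe, trF1, vlF1))
      if (vlF1 > bestVlF1) {
        bestVlF1 <- vlF1; bestParams <- P; f1Stall <- 0L
      } else f1Stall <- f1Stall + 1L
      if (stage == 1L) {
        if (vlCe < bestVlCe * (1 - schedule@relTol)) {
          bestVlCe <- vlCe; ceStall <- 0L
        } else ceStall <- ceStall + 1L
        if (ceStall >= schedule@plateauPatience) {
          stage <- 2L
          f1Stall <- 0L  # early-stop patience counts within stage 2
          if (verbose) message("switching to soft-F1 stage at epoch ", epoch)
        }
      } else if (f1Stall >= schedule@earlyStopPatience) break
    }
  })
  methods::initialize(model, params = bestParams,
                      history = do.call(rbind, history))
}

#' Per-record evaluation of a trained model
#'
#' @param model a [SeqFold2DModel-class].
#' @param records an [RnaRecordSet-class] with reference structures.
#' @param threshold binarization threshold for the predicted PPM.
#' @return data frame with one row per record: id, family, length,
#'   TP/FP/FN/TN and F1.
#' @export
evaluateModel <- function(model, records, threshold = 0.5) {
  rows <- lapply(seq_along(records@id), function(i) {
    ppm <- predictPPM(model, records@sequence[i])
    cc <- confusionCounts(binarizePPM(ppm, threshold), pairsToMatrix(records, i))
    data.frame(id = records@id[i], family = records@family[i],
               length = nchar(records@sequence[i]),
               TP = cc["TP"], FP = cc["FP"], FN = cc["FN"], TN = cc["TN"],
               f1 = f1Score(cc), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Serialize a TrainSchedule to YAML
#' @param schedule a [TrainSchedule-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrainSchedule <- function(schedule, path) {
  yaml::write_yaml(list(
    learning_rate = schedule@learningRate,
    weight_decay = schedule@weightDecay,
    batch_size = schedule@batchSize,
    plateau_patience = schedule@plateauPatience,
    early_stop_patience = schedule@earlyStopPatience,
    rel_tol = schedule@relTol, max_epochs = schedule@maxEpochs,
    eval_cap = schedule@evalCap, clip_norm = schedule@clipNorm,
    stage2_lr_factor = schedule@stage2LrFactor, seed = schedule@seed), path)
  invisible(path)
}

#' Read a TrainSchedule from YAML
#' @param path file written by [writeTrainSchedule()].
#' @return a [TrainSchedule-class].
#' @export
readTrainSchedule <- function(path) {
  y <- yaml::read_yaml(path)
  TrainSchedule(learningRate = y$learning_rate, weightDecay = y$weight_decay,
                batchSize = y$batch_size,
                plateauPatience = y$plateau_patience,
                earlyStopPatience = y$early_stop_patience,
                relTol = y$rel_tol, maxEpochs = y$max_epochs,
                evalCap = y$eval_cap, clipNorm = y$clip_norm,
                stage2LrFactor = y$stage2_lr_factor, seed = y$seed)
}
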