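#' @include AllClasses.R AllGenerics.R curation.R seqfold2d.R metrics.R
NULL

#' Run one end-to-end experiment at a similarity level
#'
#' Composes the full workflow: corpus generation (or use of a supplied
#' corpus), curation for the requested similarity level (length filter and
#' exact deduplication always; greedy 80\% clustering to representatives
#' for the cross-cluster and cross-family levels), TR/VL/TS splitting,
#' two-stage training, per-record evaluation and summary statistics.
#' Deterministic given `(corpus or corpus config, model config, schedule,
#' seed)`: the global seed fans out to the split and training stages by
#' fixed offsets so stages can be reproduced in isolation.
#'
#' @param corpus an [RnaRecordSet-class], or a [CorpusConfig-class] from
#'   which one is generated.
#' @param level similarity level (`"cross_sequence"`, `"cross_cluster"`,
#'   `"cross_family"`).
#' @param modelConfig a [ModelConfig-class].
#' @param schedule a [TrainSchedule-class]; its seed is overridden by the
#'   experiment seed.
#' @param holdoutFamily held-out family for the cross-family level
#'   (default: the family with the median population share).
#' @param seed global experiment seed.
#' @param identityCutoff clustering/removal threshold for the
#'   cross-cluster and cross-family levels.
#' @param outDir optional directory; when given, the full report bundle
#'   is written there: split (JSON), per-record metrics (TSV), summary
#'   (JSON), training history (CSV), model checkpoint (RDS with the
#'   config embedded), PSI/PSSI generalizability curves (CSV) and a run
#'   log with all derived seeds and versions (JSON).
#' @param verbose print training progress.
#' @return list with elements `split`, `model`, `metrics` (per-subset data
#'   frames), `summary` (tr/vl/ts mean F1, gap, PGscore), `curated`
#'   (the curated record set) and, when `outDir` is given, `gen` (the
#'   [analyzeGeneralizability()] bundle).
#' @export
runExperiment <- function(corpus, level = "cross_sequence",
                          modelConfig = ModelConfig(),
                          schedule = TrainSchedule(),
                          holdoutFamily = NULL, seed = 1L,
                          identityCutoff = 0.80, outDir = NULL,
                          verbose = FALSE) {
  seed <- as.integer(seed)
  if (methods::is(corpus, "CorpusConfig")) {
    corpus@seed <- seed + 1000L
    corpus <- generateCorpus(corpus)
  }
  curated <- dedupExact(filterLength(corpus))
  if (level %in% c("cross_cluster", "cross_family")) {
    cs <- clusterGreedy(curated, identityCutoff = identityCutoff)
    curated <- reduceToRepresentatives(curated, cs)
  }
  if (level == "cross_family" && is.null(holdoutFamily)) {
    sizes <- sort(table(curated@family), decreasing = TRUE)
    holdoutFamily <- names(sizes)[ceiling(length(sizes) / 2)]
  }
  split <- makeSplit(curated, level = level, holdoutFamily = holdoutFamily,
                     seed = seed + 2000L)
  schedule@seed <- seed + 3000L
  model <- seqFold2D(modelConfig, seed = seed + 4000L)
  model <- trainModel(model, curated[split@tr], curated[split@vl], schedule,
                      verbose = verbose)
  metrics <- list(tr = evaluateModel(model, curated[split@tr]),
                  vl = evaluateModel(model, curated[split@vl]),
                  ts = evaluateModel(model, curated[split@ts]))
  trF1 <- ensembleF1(metrics$tr$f1)
  vlF1 <- ensembleF1(metrics$vl$f1)
  tsF1 <- ensembleF1(metrics$ts$f1)
  # a degenerate run (TR F1 = 0) has no meaningful P/G decomposition
  pg <- if (trF1 > 0) pgScore(trF1, tsF1) else list(pgscore = 0)
  summary <- data.frame(level = level, tr_f1 = trF1, vl_f1 = vlF1,
                        ts_f1 = tsF1, gap = trF1 - tsF1,
                        pgscore = pg$pgscore)
  gen <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeSplitSpec(split, file.path(outDir, "split.json"))
    for (s in names(metrics))
      utils::write.table(metrics[[s]],
                         file.path(outDir, sprintf("metrics_%s.tsv", s)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(summary), file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(model@history, file.path(outDir, "history.csv"),
                     row.names = FALSE)
    saveRDS(model, file.path(outDir, "checkpoint.rds"))
    gen <- analyzeGeneralizability(model,
                                   curated[split@ts],
                                   curated[c(split@tr, split@vl)])
    utils::write.csv(gen$psi_curve, file.path(outDir, "gencurve_psi.csv"),
                     row.names = FALSE)
    utils::write.csv(gen$pssi_curve, file.path(outDir, "gencurve_pssi.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, level = level,
           corpus_seed = seed + 1000L, split_seed = seed + 2000L,
           train_seed = seed + 3000L, init_seed = seed + 4000L,
           n_tr = length(split@tr), n_vl = length(split@vl),
           n_ts = length(split@ts), epochs = nrow(model@history),
           package_version = as.character(utils::packageVersion("ppmfold")),
           r_version = R.version.string),
      file.path(outDir, "runlog.json"), auto_unbox = TRUE, digits = NA)
  }
  list(split = split, model = model, metrics = metrics, summary = summary,
       curated = curated, gen = gen)
}

#' Compare the three similarity levels on a shared corpus
#'
#' Runs [runExperiment()] once per level with the same corpus, model
#' configuration and schedule, and tabulates mean F1 per subset, the TR-TS
#' generalization gap and the PGscore.
#'
#' @param corpus an [RnaRecordSet-class] or [CorpusConfig-class].
#' @param levels at least two similarity levels.
#' @param modelConfig,schedule,seed,holdoutFamily,verbose passed through.
#' @return list with `summary` (one row per level) and `runs` (the
#'   individual experiment results).
#' @export
compareLevels <- function(corpus,
                          levels = c("cross_sequence", "cross_cluster",
                                     "cross_family"),
                          modelConfig = ModelConfig(),
                          schedule = TrainSchedule(), seed = 1L,
                          holdoutFamily = NULL, verbose = FALSE) {
  if (length(levels) < 2)
    stop("compareLevels needs at least two similarity levels")
  if (methods::is(corpus, "CorpusConfig")) {
    corpus@seed <- as.integer(seed) + 1000L
    corpus <- generateCorpus(corpus)
  }
  runs <- lapply(levels, function(lv)
    runExperiment(corpus, level = lv, modelConfig = modelConfig,
                  schedule = schedule, holdoutFamily = holdoutFamily,
                  seed = seed, verbose = verbose))
  names(runs) <- levels
  summary <- do.call(rbind, lapply(runs, `[[`, "summary"))
  rownames(summary) <- NULL
  list(summary = summary, runs = runs)
}

#' Generalizability analysis of a trained model
#'
#' Computes PSI and PSSI identity matrices between an unseen set and the
#' seen set, the threshold-dependent F1-seen curves and Pearson
#' correlations for both, and the max-PSI/max-PSSI ratio grouping.
#'
#' @param model a trained [SeqFold2DModel-class].
#' @param unseen,seen [RnaRecordSet-class] objects with reference
#'   structures.
#' @param thresholds threshold grid for [f1SeenCurve()].
#' @param ratioCutoff boundary for [ratioGroupSplit()].
#' @return list with `psi_curve`, `pssi_curve` (data frames),
#'   `ratio_groups` (from [ratioGroupSplit()]), `unseen_f1`, `seen_f1`,
#'   and the two identity matrices.
#' @export
analyzeGeneralizability <- function(model, unseen, seen,
                                    thresholds = seq(0.10, 1.00, by = 0.02),
                                    ratioCutoff = 1.08) {
  seenEval <- evaluateModel(model, seen)
  unseenEval <- evaluateModel(model, unseen)
  psi <- identityMatrix(unseen, seen, "PSI")
  pssi <- identityMatrix(unseen, seen, "PSSI")
  psiCurve <- f1SeenCurve(psi, seenEval$f1, unseenEval$f1, thresholds)
  pssiCurve <- f1SeenCurve(pssi, seenEval$f1, unseenEval$f1, thresholds)
  maxPsi <- apply(psi, 1, max)
  maxPssi <- apply(pssi, 1, max)
  groups <- ratioGroupSplit(maxPsi, maxPssi, unseenEval$f1,
                            cutoff = ratioCutoff)
  list(psi_curve = psiCurve, pssi_curve = pssiCurve, ratio_groups = groups,
       unseen_f1 = unseenEval$f1, seen_f1 = seenEval$f1,
       psi = psi, pssi = pssi)
}
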