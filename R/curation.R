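#' @include AllClasses.R AllGenerics.R
NULL

# default global-alignment scoring shared by clustering and PSI analysis
DEFAULT_SCORING <- list(match = 1, mismatch = -1, gapOpen = -2, gapExtend = -1)

# run expr under a temporary RNG state so callers' streams are untouched
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Exclude records longer than a length cutoff
#'
#' @param x an [RnaRecordSet-class].
#' @param maxLen inclusive length bound (default 600 nt).
#' @return the filtered set.
#' @export
filterLength <- function(x, maxLen = 600L) {
  x[nchar(x@sequence) <= maxLen]
}

#' Remove exact duplicate sequences
#'
#' Keeps the first occurrence of every distinct sequence string (the NR100
#' reduction); drops are reported with a message.
#'
#' @param x an [RnaRecordSet-class].
#' @return the deduplicated set.
#' @export
dedupExact <- function(x) {
  dup <- duplicated(x@sequence)
  if (any(dup))
    message(sprintf("dedupExact: dropped %d duplicate sequence(s)", sum(dup)))
  x[!dup]
}

kmerSet <- function(seq, word) {
  L <- nchar(seq)
  if (L < word) return(character(0))
  unique(substring(seq, seq_len(L - word + 1L), word:L))
}

#' Greedy incremental identity clustering
#'
#' CD-HIT-style clustering: records are processed in order of decreasing
#' length (ties by id); each record joins the first existing cluster whose
#' representative shares at least one `word`-mer with it *and* aligns at
#' `identityCutoff` or higher (identical aligned nucleotides divided by
#' the shorter sequence length, the CD-HIT convention); otherwise it
#' founds a new cluster. The short-word prefilter reproduces the known
#' missed-match behaviour of word-counting clusterers: highly similar
#' pairs without a shared word survive as distinct clusters.
#'
#' @param x an [RnaRecordSet-class] (non-empty).
#' @param identityCutoff identity threshold in (0, 1].
#' @param word prefilter word length.
#' @param scoring alignment scoring list (match, mismatch, gapOpen, gapExtend).
#' @return a [ClusterSet-class].
#' @export
clusterGreedy <- function(x, identityCutoff = 0.80, word = 5L,
                          scoring = DEFAULT_SCORING) {
  if (length(x) == 0) stop("cannot cluster an empty record set")
  if (identityCutoff <= 0 || identityCutoff > 1)
    stop("identityCutoff must be in (0, 1]")
  ord <- order(-nchar(x@sequence), x@id)
  ids <- x@id[ord]
  seqs <- x@sequence[ord]
  words <- lapply(seqs, kmerSet, word = word)
  repIdx <- integer(0)           # indices (into ord) of representatives
  assignment <- integer(length(ids))
  for (i in seq_along(ids)) {
    joined <- 0L
    for (r in repIdx) {
      if (!any(words[[i]] %in% words[[r]])) next
      aln <- .nw_align_cpp(seqs[i], seqs[r], scoring$match, scoring$mismatch,
                           scoring$gapOpen, scoring$gapExtend)
      idy <- aln[["matches"]] / min(nchar(seqs[i]), nchar(seqs[r]))
      if (idy >= identityCutoff) { joined <- r; break }
    }
    if (joined == 0L) { repIdx <- c(repIdx, i); joined <- i }
    assignment[i] <- joined
  }
  new("ClusterSet", member = ids, representative = ids[assignment])
}

#' Reduce a record set to its cluster representatives
#'
#' @param x an [RnaRecordSet-class].
#' @param clusterSet a [ClusterSet-class] from [clusterGreedy()].
#' @return the subset of `x` containing one representative per cluster,
#'   with the `cluster` field set to the representative id.
#' @export
reduceToRepresentatives <- function(x, clusterSet) {
  out <- x[clusterRepresentatives(clusterSet)]
  out@cluster <- out@id
  out
}

#' Remove test records similar to a training set
#'
#' Drops every test record whose maximum alignment identity to any
#' training record reaches `identityCutoff` (identity over the shorter
#' sequence, matching the clustering convention).
#'
#' @param testRecords,trainRecords non-empty [RnaRecordSet-class] objects.
#' @param identityCutoff removal threshold.
#' @param scoring alignment scoring list.
#' @return the filtered test set.
#' @export
filterCrossSet <- function(testRecords, trainRecords, identityCutoff = 0.80,
                           scoring = DEFAULT_SCORING) {
  if (length(testRecords) == 0 || length(trainRecords) == 0)
    stop("both record sets must be non-empty")
  idm <- .nw_identity_matrix_cpp(testRecords@sequence, trainRecords@sequence,
                                 scoring$match, scoring$mismatch,
                                 scoring$gapOpen, scoring$gapExtend, 1L)
  keep <- apply(idm, 1, max) < identityCutoff
  if (any(!keep))
    message(sprintf("filterCrossSet: removed %d test record(s) at identity >= %.2f",
                    sum(!keep), identityCutoff))
  testRecords[keep]
}

#' Split records into training, validation and test sets
#'
#' At the `cross_sequence` and `cross_cluster` levels the ids are randomly
#' partitioned at `ratios` (the caller is responsible for having applied
#' the appropriate redundancy reduction first). At the `cross_family`
#' level the entire held-out family becomes the test set and the remaining
#' records are randomly split into TR/VL at `ratios[1:2]` renormalised
#' (70/15 becomes 82.4\%/17.6\%).
#'
#' @param x an [RnaRecordSet-class].
#' @param level one of `"cross_sequence"`, `"cross_cluster"`, `"cross_family"`.
#' @param ratios TR/VL/TS proportions summing to 1.
#' @param holdoutFamily family name (required when `level = "cross_family"`).
#' @param seed integer seed; the same seed always yields the same split.
#' @param stratifyByFamily if `TRUE`, random splits are drawn within each
#'   family and merged, preserving family shares across subsets.
#' @return a [SplitSpec-class].
#' @export
makeSplit <- function(x, level = c("cross_sequence", "cross_cluster",
                                   "cross_family"),
                      ratios = c(0.70, 0.15, 0.15), holdoutFamily = NULL,
                      seed = 1L, stratifyByFamily = FALSE) {
  level <- match.arg(level)
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  seed <- as.integer(seed)
  if (level == "cross_family") {
    if (is.null(holdoutFamily)) stop("cross_family requires holdoutFamily")
    if (!holdoutFamily %in% x@family)
      stop("unknown family: ", holdoutFamily)
    tsIds <- x@id[!is.na(x@family) & x@family == holdoutFamily]
    rest <- setdiff(x@id, tsIds)
    frac <- ratios[1] / (ratios[1] + ratios[2])
    part <- withSeed(seed, {
      n <- length(rest)
      idx <- sample.int(n)
      ntr <- round(frac * n)
      list(tr = rest[idx[seq_len(ntr)]], vl = rest[idx[-seq_len(ntr)]])
    })
    return(new("SplitSpec", level = level, tr = part$tr, vl = part$vl,
               ts = tsIds, holdoutFamily = holdoutFamily, seed = seed))
  }
  splitIds <- function(ids) {
    n <- length(ids)
    idx <- sample.int(n)
    ntr <- round(ratios[1] * n)
    nvl <- round(ratios[2] * n)
    nvl <- min(nvl, n - ntr)
    list(tr = ids[idx[seq_len(ntr)]],
         vl = ids[idx[ntr + seq_len(nvl)]],
         ts = ids[idx[setdiff(seq_len(n), seq_len(ntr + nvl))]])
  }
  part <- withSeed(seed, {
    if (stratifyByFamily && !all(is.na(x@family))) {
      per <- lapply(split(x@id, x@family), splitIds)
      list(tr = unlist(lapply(per, `[[`, "tr"), use.names = FALSE),
           vl = unlist(lapply(per, `[[`, "vl"), use.names = FALSE),
           ts = unlist(lapply(per, `[[`, "ts"), use.names = FALSE))
    } else splitIds(x@id)
  })
  new("SplitSpec", level = level, tr = part$tr, vl = part$vl, ts = part$ts,
      holdoutFamily = NA_character_, seed = seed)
}

#' Serialize a SplitSpec to JSON
#' @param split a [SplitSpec-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSplitSpec <- function(split, path) {
  jsonlite::write_json(list(level = split@level, seed = split@seed,
                            holdout_family = split@holdoutFamily,
                            tr = split@tr, vl = split@vl, ts = split@ts),
                       path, auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a SplitSpec from JSON
#' @param path file written by [writeSplitSpec()].
#' @return a [SplitSpec-class].
#' @export
readSplitSpec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SplitSpec", level = j$level,
      tr = as.character(j$tr), vl = as.character(j$vl),
      ts = as.character(j$ts),
      holdoutFamily = if (is.null(j$holdout_family)) NA_character_
                      else as.character(j$holdout_family),
      seed = as.integer(j$seed))
}

#' Write cluster membership as a two-column TSV
#' @param clusterSet a [ClusterSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeClusterSet <- function(clusterSet, path) {
  utils::write.table(clusterMembership(clusterSet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
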