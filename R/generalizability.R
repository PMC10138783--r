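#' @include AllClasses.R AllGenerics.R curation.R
NULL

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (defaults: match +1,
#' mismatch -1, gap open -2, gap extend -1). The percentage sequence
#' identity (PSI) is the number of identical aligned nucleotides divided
#' by the mean length of the pair; `denom = "shorter"` divides by the
#' shorter length instead (the clustering convention). Among equally
#' scoring alignments the one with the most identities is reported, so the
#' value is deterministic.
#'
#' @param seqA,seqB non-empty sequences.
#' @param scoring list with `match`, `mismatch`, `gapOpen`, `gapExtend`.
#' @param denom `"mean"` or `"shorter"`.
#' @return list with `identity`, `matches` and `score`.
#' @export
alignIdentity <- function(seqA, seqB, scoring = DEFAULT_SCORING,
                          denom = c("mean", "shorter")) {
  denom <- match.arg(denom)
  if (nchar(seqA) == 0 || nchar(seqB) == 0) stop("empty sequence")
  aln <- .nw_align_cpp(seqA, seqB, scoring$match, scoring$mismatch,
                       scoring$gapOpen, scoring$gapExtend)
  den <- if (denom == "shorter") min(nchar(seqA), nchar(seqB))
         else mean(c(nchar(seqA), nchar(seqB)))
  list(identity = unname(aln[["matches"]]) / den,
       matches = unname(aln[["matches"]]), score = unname(aln[["score"]]))
}

STRUCT_SCORING <- list(match = 1, mismatch = -1, gapOpen = -1, gapExtend = -1)

#' Secondary-structure alignment identity
#'
#' Global alignment over the three-letter structure alphabet `(`, `)`,
#' `.` with match +1, mismatch -1, gap -1 (linear). The percentage
#' secondary structure identity (PSSI) is the number of identical aligned
#' structure characters over the mean length. Inputs must be balanced,
#' pseudoknot-free dot-bracket strings.
#'
#' @param dbA,dbB non-empty dot-bracket strings.
#' @return scalar PSSI in `[0, 1]`.
#' @export
alignStructureIdentity <- function(dbA, dbB) {
  if (nchar(dbA) == 0 || nchar(dbB) == 0) stop("empty structure string")
  for (db in c(dbA, dbB)) {
    dotBracketToPairs(db)  # errors on unbalanced input
    if (grepl("[][{}<>]", db))
      stop("structure alignment expects pseudoknot-free '()' strings")
  }
  aln <- .nw_align_cpp(dbA, dbB, STRUCT_SCORING$match, STRUCT_SCORING$mismatch,
                       STRUCT_SCORING$gapOpen, STRUCT_SCORING$gapExtend)
  unname(aln[["matches"]]) / mean(c(nchar(dbA), nchar(dbB)))
}

recordDotBrackets <- function(x) {
  vapply(seq_along(x@id), function(i)
    pairsToDotBracket(x@pairs[[i]], nchar(x@sequence[i])), "")
}

#' All-pairs identity matrix between unseen and seen record sets
#'
#' Computes every unseen-by-seen alignment identity; the result does not
#' depend on evaluation order. `kind = "PSI"` aligns sequences (affine
#' gaps, mean-length denominator); `kind = "PSSI"` aligns dot-bracket
#' structure strings. Optionally cached: when `cacheFile` exists it is
#' read back instead of recomputing.
#'
#' @param unseen,seen non-empty [RnaRecordSet-class] objects.
#' @param kind `"PSI"` or `"PSSI"`.
#' @param scoring sequence-alignment scoring (PSI only).
#' @param cacheFile optional TSV cache path.
#' @return numeric matrix (rows = unseen ids, columns = seen ids).
#' @export
identityMatrix <- function(unseen, seen, kind = c("PSI", "PSSI"),
                           scoring = DEFAULT_SCORING, cacheFile = NULL) {
  kind <- match.arg(kind)
  if (length(unseen) == 0 || length(seen) == 0)
    stop("both record sets must be non-empty")
  if (!is.null(cacheFile) && file.exists(cacheFile)) {
    tab <- utils::read.table(cacheFile, header = TRUE, sep = "\t")
    m <- matrix(tab$identity, nrow = length(unique(tab$unseen_id)),
                byrow = TRUE,
                dimnames = list(unique(tab$unseen_id), unique(tab$seen_id)))
    return(m)
  }
  if (kind == "PSI") {
    m <- .nw_identity_matrix_cpp(unseen@sequence, seen@sequence,
                                 scoring$match, scoring$mismatch,
                                 scoring$gapOpen, scoring$gapExtend, 0L)
  } else {
    m <- .nw_identity_matrix_cpp(recordDotBrackets(unseen),
                                 recordDotBrackets(seen),
                                 STRUCT_SCORING$match, STRUCT_SCORING$mismatch,
                                 STRUCT_SCORING$gapOpen,
                                 STRUCT_SCORING$gapExtend, 0L)
  }
  dimnames(m) <- list(unseen@id, seen@id)
  if (!is.null(cacheFile)) {
    tab <- data.frame(unseen_id = rep(rownames(m), each = ncol(m)),
                      seen_id = rep(colnames(m), nrow(m)),
                      identity = as.vector(t(m)))
    utils::write.table(tab, cacheFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  m
}

#' Threshold-dependent F1-seen curve
#'
#' For each unseen record `u` and threshold `t`, the informed seen subset
#' is `S_t(u) = {s : id(u, s) >= t}` and the F1-seen score is the
#' identity-weighted mean of the F1 scores of `S_t(u)` (null when the
#' subset is empty; nulls are excluded from the ratio and the
#' correlation). `f1_ratio(t)` is the ratio of means: mean F1-unseen over
#' mean F1-seen across informed records; `pcc(t)` is the Pearson
#' correlation of the informed (F1-seen, F1-unseen) pairs, recorded as
#' `NA` (with a message) when fewer than 3 pairs are informed.
#'
#' @param idMat identity matrix from [identityMatrix()] (unseen x seen).
#' @param seenF1 numeric vector of seen-set F1 scores (length `ncol(idMat)`).
#' @param unseenF1 numeric vector of unseen F1 scores (length `nrow(idMat)`).
#' @param thresholds ascending threshold grid in (0, 1].
#' @return data frame with columns `threshold`, `f1_ratio`, `pcc`,
#'   `n_informed`.
#' @export
f1SeenCurve <- function(idMat, seenF1, unseenF1,
                        thresholds = seq(0.10, 1.00, by = 0.02)) {
  stopifnot(length(seenF1) == ncol(idMat), length(unseenF1) == nrow(idMat))
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  rows <- lapply(thresholds, function(t) {
    f1seen <- vapply(seq_len(nrow(idMat)), function(u) {
      w <- idMat[u, ]
      sel <- w >= t
      if (!any(sel)) return(NA_real_)
      sum(w[sel] * seenF1[sel]) / sum(w[sel])
    }, 1)
    informed <- !is.na(f1seen)
    n <- sum(informed)
    ratio <- if (n > 0) mean(unseenF1[informed]) / mean(f1seen[informed])
             else NA_real_
    pcc <- if (n >= 3 && stats::sd(f1seen[informed]) > 0 &&
               stats::sd(unseenF1[informed]) > 0)
      stats::cor(f1seen[informed], unseenF1[informed]) else NA_real_
    if (n > 0 && n < 3)
      message(sprintf("threshold %.2f: only %d informed pair(s); PCC null",
                      t, n))
    data.frame(threshold = t, f1_ratio = ratio, pcc = pcc, n_informed = n)
  })
  do.call(rbind, rows)
}

#' Split unseen records by sequence-to-structure similarity ratio
#'
#' Each unseen record is characterised by its maximum PSI and maximum
#' PSSI against the seen set. Records with `maxPSI / maxPSSI > cutoff`
#' form the low-structure-similarity group; the rest (ratio at or below
#' the cutoff) the high-structure-similarity group. Records with zero
#' maximum PSSI are excluded with a message.
#'
#' @param maxPsi,maxPssi named numeric vectors (one value per unseen id).
#' @param f1 numeric vector of unseen F1 scores, parallel to `maxPsi`.
#' @param cutoff ratio boundary (default 1.08; the boundary itself goes to
#'   the high-structure group).
#' @return list with `groups` (data frame: id, max_psi, max_pssi, ratio,
#'   f1, group) and `summary` (per-group n and mean F1).
#' @export
ratioGroupSplit <- function(maxPsi, maxPssi, f1, cutoff = 1.08) {
  stopifnot(length(maxPsi) == length(maxPssi), length(f1) == length(maxPsi))
  ok <- maxPssi > 0
  if (any(!ok))
    message(sprintf("ratioGroupSplit: excluded %d record(s) with zero PSSI",
                    sum(!ok)))
  ratio <- maxPsi[ok] / maxPssi[ok]
  group <- ifelse(ratio > cutoff, "low_structure", "high_structure")
  groups <- data.frame(id = names(maxPsi)[ok] %||% which(ok),
                       max_psi = maxPsi[ok], max_pssi = maxPssi[ok],
                       ratio = ratio, f1 = f1[ok], group = group,
                       row.names = NULL)
  summary <- do.call(rbind, lapply(split(groups, groups$group), function(g)
    data.frame(group = g$group[1], n = nrow(g), mean_f1 = mean(g$f1))))
  rownames(summary) <- NULL
  list(groups = groups, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
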