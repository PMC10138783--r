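#' @include AllClasses.R AllGenerics.R
NULL

BRACKET_TIERS <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))

#' Read RNA sequence/structure records
#'
#' Supported formats: `dotbracket` (2-3 line records `>id` / sequence /
#' optional structure; bracket tiers `()[]{}<>` all parsed), `ct`
#' (connectivity table, 1-based partner column), `bpseq` (`index base
#' partner`), and `fasta` (sequence only, parsed with Biostrings). `T` is
#' mapped to `U`. When a raw file assigns more than one partner to a base
#' (a multiplet), the first-listed partner is kept and the rest dropped
#' with a message; inconsistent duplicate lines are a parse error naming
#' the offending line.
#'
#' @param path file to read.
#' @param format one of `"dotbracket"`, `"ct"`, `"bpseq"`, `"fasta"`.
#' @return an [RnaRecordSet-class].
#' @export
readRnaRecords <- function(path,
                           format = c("dotbracket", "ct", "bpseq", "fasta")) {
  format <- match.arg(format)
  switch(format,
    dotbracket = readDotBracket(path),
    ct = readCt(path),
    bpseq = readBpseq(path),
    fasta = {
      ss <- Biostrings::readBStringSet(path)
      RnaRecordSet(id = sub("\\s.*$", "", names(ss)), sequence = ss)
    })
}

#' Write RNA records
#'
#' Emits the same dialects [readRnaRecords()] accepts, so that a
#' read-write-read round trip is the identity. Pseudoknotted records are
#' written in dot-bracket using up to four bracket tiers.
#'
#' @param x an [RnaRecordSet-class].
#' @param path output file.
#' @param format one of `"dotbracket"`, `"ct"`, `"bpseq"`, `"fasta"`.
#' @return `path`, invisibly.
#' @export
writeRnaRecords <- function(x, path,
                            format = c("dotbracket", "ct", "bpseq", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(rnaSequences(x))
    Biostrings::writeXStringSet(ss, path)
    return(invisible(path))
  }
  lines <- switch(format,
    dotbracket = unlist(lapply(seq_along(x@id), function(i) {
      c(paste0(">", x@id[i]), x@sequence[i],
        pairsToDotBracket(x@pairs[[i]], nchar(x@sequence[i])))
    })),
    ct = unlist(lapply(seq_along(x@id), function(i) {
      L <- nchar(x@sequence[i])
      partner <- integer(L)
      p <- x@pairs[[i]]
      partner[p[, 1]] <- p[, 2]; partner[p[, 2]] <- p[, 1]
      bases <- strsplit(x@sequence[i], "")[[1]]
      c(sprintf("%d %s", L, x@id[i]),
        sprintf("%d %s %d %d %d %d", seq_len(L), bases, seq_len(L) - 1L,
                c(seq_len(L)[-1L], 0L), partner, seq_len(L)))
    })),
    bpseq = unlist(lapply(seq_along(x@id), function(i) {
      L <- nchar(x@sequence[i])
      partner <- integer(L)
      p <- x@pairs[[i]]
      partner[p[, 1]] <- p[, 2]; partner[p[, 2]] <- p[, 1]
      bases <- strsplit(x@sequence[i], "")[[1]]
      c(paste0("# ", x@id[i]),
        sprintf("%d %s %d", seq_len(L), bases, partner))
    })))
  writeLines(lines, path)
  invisible(path)
}

readDotBracket <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no '>' headers found in ", path)
  ids <- character(0); seqs <- character(0); pairs <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    body <- lines[(starts[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) < 1 || length(body) > 2)
      stop(sprintf("record at line %d must have 1 sequence line and at most 1 structure line",
                   lineno[starts[k]]))
    ids <- c(ids, sub("^>\\s*", "", lines[starts[k]]))
    seqs <- c(seqs, body[1])
    if (length(body) == 2) {
      if (nchar(body[2]) != nchar(body[1]))
        stop(sprintf("structure length mismatch at line %d",
                     lineno[starts[k] + 2L]))
      pairs[[k]] <- dotBracketToPairs(body[2], line = lineno[starts[k] + 2L])
    } else pairs[[k]] <- emptyPairs()
  }
  RnaRecordSet(id = ids, sequence = seqs, pairs = pairs)
}

#' Convert a dot-bracket string to a pair matrix
#'
#' All four bracket tiers `()`, `[]`, `{}`, `<>` are matched
#' independently, so pseudoknotted structures are representable.
#'
#' @param db dot-bracket string.
#' @param line line number used in error messages.
#' @return two-column integer matrix of 1-based pairs, `i < j`.
#' @export
dotBracketToPairs <- function(db, line = NA_integer_) {
  chars <- strsplit(db, "")[[1]]
  where <- if (is.na(line)) "" else sprintf(" at line %d", line)
  out <- emptyPairs()
  for (tier in BRACKET_TIERS) {
    stack <- integer(0)
    for (pos in seq_along(chars)) {
      if (chars[pos] == tier[1]) stack <- c(stack, pos)
      else if (chars[pos] == tier[2]) {
        if (length(stack) == 0)
          stop(sprintf("unbalanced '%s'%s (position %d)", tier[2], where, pos))
        out <- rbind(out, c(stack[length(stack)], pos))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0)
      stop(sprintf("unbalanced '%s'%s (position %d)", tier[1], where, stack[1]))
  }
  bad <- setdiff(unique(chars), c(".", "-", unlist(BRACKET_TIERS)))
  if (length(bad) > 0)
    stop(sprintf("unknown structure character '%s'%s", bad[1], where))
  normalizePairs(out)
}

#' Convert a nested pair matrix to a dot-bracket string
#'
#' Pairs are assigned greedily to the first bracket tier in which they do
#' not cross a previously assigned pair, so nested structures use `()`
#' only and pseudoknots spill into `[]`, `{}`, `<>`.
#'
#' @param pairs two-column integer matrix (1-based, `i < j`).
#' @param L sequence length.
#' @return a dot-bracket string of length `L`.
#' @export
pairsToDotBracket <- function(pairs, L) {
  chars <- rep(".", L)
  pairs <- normalizePairs(pairs)
  tiers <- vector("list", length(BRACKET_TIERS))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    placed <- FALSE
    for (t in seq_along(tiers)) {
      crossing <- FALSE
      for (q in tiers[[t]]) {
        k <- q[1]; l <- q[2]
        if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) {
          crossing <- TRUE; break
        }
      }
      if (!crossing) {
        tiers[[t]] <- c(tiers[[t]], list(c(i, j)))
        chars[i] <- BRACKET_TIERS[[t]][1]
        chars[j] <- BRACKET_TIERS[[t]][2]
        placed <- TRUE; break
      }
    }
    if (!placed) stop("structure needs more than 4 bracket tiers")
  }
  paste(chars, collapse = "")
}

# shared parser for CT/BPSEQ position tables; lenient about dialects:
# records are opened by header lines, or implicitly (id from filename)
# for headerless single-molecule files
parsePositionTable <- function(path, is_data, id_from, partner_col, base_col) {
  lines <- readLines(path)
  recs <- list(); cur <- NULL
  flush <- function(cur, recs) {
    if (is.null(cur) || length(cur$base) == 0) return(recs)
    c(recs, list(cur))
  }
  newRec <- function(id) list(id = id, base = character(0),
                              lastIdx = 0L, claims = list())
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt)) next
    tok <- strsplit(txt, "\\s+")[[1]]
    if (!is_data(tok)) {
      recs <- flush(cur, recs)
      cur <- newRec(id_from(tok))
      next
    }
    idx <- suppressWarnings(as.integer(tok[1]))
    if (is.na(idx)) stop(sprintf("line %d: expected a position index", ln))
    if (is.null(cur)) cur <- newRec(sub("\\.[^.]*$", "", basename(path)))
    if (idx == 1L && cur$lastIdx > 0L) {  # headerless record boundary
      recs <- flush(cur, recs)
      cur <- newRec(sprintf("%s_%d", sub("\\.[^.]*$", "", basename(path)),
                            length(recs) + 1L))
    }
    if (idx != cur$lastIdx + 1L)
      stop(sprintf("line %d: non-monotone position index %d (expected %d)",
                   ln, idx, cur$lastIdx + 1L))
    cur$lastIdx <- idx
    cur$base <- c(cur$base, tok[base_col])
    prt <- suppressWarnings(as.integer(tok[partner_col]))
    if (is.na(prt)) stop(sprintf("line %d: bad partner field", ln))
    cur$claims[[length(cur$claims) + 1L]] <- c(idx, prt, ln)
  }
  recs <- flush(cur, recs)
  if (length(recs) == 0) stop("no records found in ", path)
  ids <- vapply(recs, `[[`, "", "id")
  seqs <- vapply(recs, function(r) paste(r$base, collapse = ""), "")
  pairs <- lapply(recs, function(r) {
    L <- length(r$base)
    seen_exact <- character(0)
    used <- logical(L)
    keep <- emptyPairs()
    dropped <- 0L
    for (cl in r$claims) {
      idx <- cl[1]; prt <- cl[2]; ln <- cl[3]
      if (prt == 0L) next
      if (prt < 1L || prt > L)
        stop(sprintf("line %d: partner %d out of range", ln, prt))
      key <- paste(min(idx, prt), max(idx, prt))
      if (key %in% seen_exact) next  # the reciprocal half of a kept pair
      if (used[idx] || used[prt]) { dropped <- dropped + 1L; next }
      keep <- rbind(keep, c(min(idx, prt), max(idx, prt)))
      used[idx] <- TRUE; used[prt] <- TRUE
      seen_exact <- c(seen_exact, key)
    }
    if (dropped > 0)
      message(sprintf("record %s: dropped %d multiplet partner assignment(s), keeping first-listed",
                      r$id, dropped))
    normalizePairs(keep)
  })
  RnaRecordSet(id = ids, sequence = seqs, pairs = pairs)
}

readCt <- function(path) {
  # CT data line: "i base prev next partner i"; anything else is a header
  parsePositionTable(path,
    is_data = function(tok) {
      length(tok) >= 6 && nchar(tok[2]) == 1 &&
        !is.na(suppressWarnings(as.integer(tok[1]))) &&
        !is.na(suppressWarnings(as.integer(tok[5])))
    },
    id_from = function(tok) paste(tok[-1], collapse = " "),
    partner_col = 5L, base_col = 2L)
}

readBpseq <- function(path) {
  # BPSEQ data line: "i base partner"; '#'-prefixed lines are headers
  parsePositionTable(path,
    is_data = function(tok) {
      !grepl("^#", tok[1]) && length(tok) >= 3 && nchar(tok[2]) == 1 &&
        !is.na(suppressWarnings(as.integer(tok[1]))) &&
        !is.na(suppressWarnings(as.integer(tok[3])))
    },
    id_from = function(tok) trimws(sub("^#\\s*", "", paste(tok, collapse = " "))),
    partner_col = 3L, base_col = 2L)
}

#' Expand a record's pair list to a binary L x L matrix
#'
#' @param x an [RnaRecordSet-class].
#' @param i record index or id (default first record).
#' @return symmetric binary matrix with zero diagonal; `M[i, j] = 1` iff
#'   bases `i` and `j` are paired.
#' @export
pairsToMatrix <- function(x, i = 1L) {
  if (methods::is(x, "RnaRecordSet")) {
    rec <- x[i]
    L <- nchar(rec@sequence[1])
    p <- rec@pairs[[1]]
  } else stop("x must be an RnaRecordSet")
  M <- matrix(0, L, L)
  if (nrow(p) > 0) {
    M[p] <- 1
    M[p[, 2:1, drop = FALSE]] <- 1
  }
  M
}

#' Recover the pair list of a binary pairing matrix
#'
#' @param M symmetric binary matrix.
#' @return two-column integer matrix of 1-based pairs, `i < j`.
#' @export
matrixToPairs <- function(M) {
  w <- which(M != 0 & upper.tri(M), arr.ind = TRUE)
  normalizePairs(w)
}

#' Drop non-canonical base pairs
#'
#' Retains only pairs whose bases form AU, GC or GU (either orientation).
#' Pairs involving ambiguity codes are dropped: canonicity cannot be
#' certified. Idempotent.
#'
#' @param x an [RnaRecordSet-class].
#' @return the filtered [RnaRecordSet-class].
#' @export
removeNonCanonical <- function(x) {
  x@pairs <- lapply(seq_along(x@id), function(i) {
    p <- x@pairs[[i]]
    if (nrow(p) == 0) return(p)
    b <- strsplit(x@sequence[i], "")[[1]]
    keep <- paste0(b[p[, 1]], b[p[, 2]]) %in% CANONICAL_PAIRS
    p[keep, , drop = FALSE]
  })
  methods::validObject(x)
  x
}

#' Remove pseudoknots by exact maximum nested subset
#'
#' For each record, returns the nested (non-crossing) subset of its pairs
#' of maximum cardinality, computed by interval dynamic programming; ties
#' are resolved toward the lexicographically smallest retained pair list.
#'
#' @param x an [RnaRecordSet-class].
#' @return the de-knotted [RnaRecordSet-class].
#' @export
removePseudoknots <- function(x) {
  x@pairs <- lapply(seq_along(x@id), function(i) {
    p <- x@pairs[[i]]
    if (nrow(p) < 2) return(p)
    keep <- .max_nested_cpp(p, nchar(x@sequence[i]))
    normalizePairs(p[keep, , drop = FALSE])
  })
  methods::validObject(x)
  x
}
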