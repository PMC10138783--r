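# Independent brute-force oracles used to certify the DP implementations.

CANON <- c("AU", "UA", "GC", "CG", "GU", "UG")

canPair <- function(a, b) paste0(a, b) %in% CANON

# maximum number of nested canonical pairs by explicit recursion over
# "position i unpaired, or i paired with l" decompositions (no memo)
bruteNussinovMax <- function(seq, minLoop = 3L) {
  b <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i <= minLoop) return(0L)
    best <- rec(i + 1L, j)
    for (l in (i + minLoop + 1L):j) {
      if (canPair(b[i], b[l])) {
        v <- 1L + (if (l > i + 1L) rec(i + 1L, l - 1L) else 0L) +
          (if (l < j) rec(l + 1L, j) else 0L)
        if (v > best) best <- v
      }
    }
    best
  }
  if (length(b) < 2) return(0L)
  rec(1L, length(b))
}

crossingPairs <- function(p) {
  if (nrow(p) < 2) return(FALSE)
  for (a in seq_len(nrow(p) - 1)) {
    for (bb in (a + 1):nrow(p)) {
      i <- p[a, 1]; j <- p[a, 2]; k <- p[bb, 1]; l <- p[bb, 2]
      if ((i < k && k < j && j < l) || (k < i && i < l && l < j))
        return(TRUE)
    }
  }
  FALSE
}

# maximum-cardinality nested subset by enumeration over all 2^k subsets
bruteMaxNestedSize <- function(pairs) {
  k <- nrow(pairs)
  if (k == 0) return(0L)
  best <- 0L
  for (mask in 0:(2^k - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(sel) <= best) next
    if (!crossingPairs(pairs[sel, , drop = FALSE])) best <- length(sel)
  }
  best
}

# enumerate every global alignment of a and b; return the maximum score
# and, among maximum-score alignments, the maximum number of identities
bruteAlign <- function(a, b, match = 1, mismatch = -1,
                       gapOpen = -2, gapExtend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- c(score = -Inf, matches = 0)
  # state: positions consumed (i, j), running score, matches, last move
  rec <- function(i, j, score, matches, last) {
    if (i > length(av) && j > length(bv)) {
      if (score > best[1] || (score == best[1] && matches > best[2]))
        best <<- c(score, matches)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      eq <- av[i] == bv[j]
      rec(i + 1, j + 1, score + if (eq) match else mismatch,
          matches + eq, "m")
    }
    if (i <= length(av))
      rec(i + 1, j, score + if (last == "x") gapExtend else gapOpen,
          matches, "x")
    if (j <= length(bv))
      rec(i, j + 1, score + if (last == "y") gapExtend else gapOpen,
          matches, "y")
  }
  rec(1, 1, 0, 0, "none")
  best
}

# two-sample KS statistic straight from the empirical CDF definition
bruteKS <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), 1)
  Fy <- vapply(grid, function(g) mean(y <= g), 1)
  max(abs(Fx - Fy))
}

randomRna <- function(L) paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                               collapse = "")

# random well-formed pair set on L positions (not necessarily nested)
randomPairSet <- function(L, k) {
  pos <- sample(L, 2 * k)
  m <- matrix(pos, ncol = 2)
  t(apply(m, 1, sort))
}

tinyCorpus <- function(n = 30L, seed = 99L) {
  generateCorpus(CorpusConfig(
    nRecords = n, nFamilies = 2L, familyShares = c(0.6, 0.4),
    lengthRanges = cbind(c(25, 30), c(35, 40)),
    intraMutationRate = 0.1, clusterRedundancy = 1, seed = seed))
}

# internal helpers reused by tests
emptyPairs_ <- ppmfold:::emptyPairs
normalizePairs_ <- ppmfold:::normalizePairs

kmers_ <- function(seq, word = 5L) {
  L <- nchar(seq)
  if (L < word) return(character(0))
  unique(substring(seq, seq_len(L - word + 1L), word:L))
}
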