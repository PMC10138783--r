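#' @include AllClasses.R AllGenerics.R curation.R
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Fold a sequence with the deterministic Nussinov oracle
#'
#' Returns the maximum-cardinality nested set of canonical pairs (AU, GC,
#' GU, either orientation) separated by more than `minLoop` bases, by
#' interval dynamic programming. The traceback prefers pairing the
#' leftmost position with its smallest admissible partner, so the result
#' is unique and reproducible. Ambiguity codes never pair.
#'
#' @param sequence RNA sequence (ACGU; `T` mapped to `U`).
#' @param oracle a [FoldOracle-class].
#' @return two-column integer matrix of 1-based pairs, `i < j`.
#' @export
nussinovFold <- function(sequence, oracle = FoldOracle()) {
  sequence <- toupper(chartr("Tt", "Uu", sequence))
  normalizePairs(.nussinov_cpp(sequence, oracle@minLoop))
}

randomSequence <- function(L) {
  paste(sample(RNA_BASES, L, replace = TRUE), collapse = "")
}

#' F1 agreement between two base-pair lists
#'
#' Expands both pair lists to binary `L x L` matrices and returns their
#' element-wise F1 score; 1 for identical structures, 0 for disjoint ones.
#' Used for fold-stability probing and for classifying mutants as
#' structure-preserving or structure-breaking.
#'
#' @param pairsA,pairsB two-column integer pair matrices (1-based, i < j).
#' @param L sequence length.
#' @return scalar F1 in `[0, 1]`.
#' @export
pairListF1 <- function(pairsA, pairsB, L) {
  MA <- matrix(0, L, L)
  if (nrow(pairsA)) { MA[pairsA] <- 1; MA[pairsA[, 2:1, drop = FALSE]] <- 1 }
  MB <- matrix(0, L, L)
  if (nrow(pairsB)) { MB[pairsB] <- 1; MB[pairsB[, 2:1, drop = FALSE]] <- 1 }
  f1Score(confusionCounts(MA, MB))
}

# internal alias used by the stability sampler
pairSetF1 <- pairListF1

# mean F1 between the folds of mutants at `rate` and the ancestor's fold
foldStability <- function(anc, rate, oracle, nProbe = 8L) {
  pa <- nussinovFold(anc, oracle)
  if (nrow(pa) == 0) return(0)
  L <- nchar(anc)
  mean(vapply(seq_len(nProbe), function(i)
    pairSetF1(nussinovFold(mutateSequence(anc, rate), oracle), pa, L), 1))
}

# A random hairpin-architecture sequence: random 5' arm, random loop,
# complementary 3' arm, optional random tail. Real RNA families are
# organised around such conserved stems; uniform-random sequences almost
# never carry a mutation-robust maximum-matching fold.
randomHairpinAncestor <- function(L, oracle) {
  loop <- sample(max(3L, oracle@minLoop):(oracle@minLoop + 4L), 1L)
  tail <- sample(0:min(4L, max(0L, L - loop - 8L)), 1L)
  k <- (L - loop - tail) %/% 2L
  slack <- L - loop - tail - 2L * k
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  arm <- sample(RNA_BASES, k, replace = TRUE)
  hp <- c(arm, sample(RNA_BASES, loop + slack, replace = TRUE), comp[rev(arm)])
  tl <- sample(RNA_BASES, tail, replace = TRUE)
  # tail on either side: families differ in where their stem sits
  if (stats::runif(1) < 0.5) paste(c(tl, hp), collapse = "")
  else paste(c(hp, tl), collapse = "")
}

# Draw a random ancestor conditioned on structural robustness: candidates
# follow a stem-biased (hairpin) architecture and are kept only when
# mutants at the family's substitution rate largely retain the fold.
# This emulates the within-family structure conservation of curated RNA
# corpora; a maximum-matching oracle applied to unconditioned random
# sequences yields near-chaotic structure labels instead.
sampleStableAncestor <- function(L, rate, target, oracle, maxTries = 60L) {
  if (target <= 0) return(randomSequence(L))
  best <- NULL; bestS <- -1
  minPairs <- max(3L, floor(L / 6))
  for (i in seq_len(maxTries)) {
    anc <- randomHairpinAncestor(L, oracle)
    if (nrow(nussinovFold(anc, oracle)) < minPairs) next
    s <- foldStability(anc, rate, oracle, nProbe = 24L)
    if (s > bestS) { best <- anc; bestS <- s }
    if (bestS >= target) break
  }
  if (is.null(best)) randomSequence(L) else best
}

#' Per-site substitution (and optional indel) mutant of a sequence
#'
#' Each position is substituted with probability `rate`, drawing uniformly
#' from the three other bases. With `indelRate > 0`, each position is
#' additionally hit by an indel (deletion of the base or insertion of a
#' random base after it, equally likely) with that probability. The
#' default is substitution-only, which keeps the expected pairwise
#' identity between mutants in closed form. Uses the current RNG stream.
#'
#' @param seq RNA sequence.
#' @param rate per-site substitution probability.
#' @param indelRate per-site insertion/deletion probability (default 0).
#' @return the mutated sequence string.
#' @export
mutateSequence <- function(seq, rate, indelRate = 0) {
  b <- strsplit(seq, "")[[1]]
  if (rate > 0) {
    hit <- stats::runif(length(b)) < rate
    if (any(hit))
      b[hit] <- vapply(b[hit],
                       function(x) sample(setdiff(RNA_BASES, x), 1L), "")
  }
  if (indelRate > 0) {
    out <- character(0)
    for (x in b) {
      if (stats::runif(1) < indelRate) {
        if (stats::runif(1) < 0.5) next                      # deletion
        out <- c(out, x, sample(RNA_BASES, 1L))              # insertion
      } else out <- c(out, x)
    }
    b <- out
  }
  paste(b, collapse = "")
}

#' Generate one synthetic RNA family
#'
#' A single uniform-random ancestor of the given length is drawn; members
#' are independent per-site substitution mutants of it at `mutationRate`,
#' each folded by the Nussinov oracle. The expected pairwise identity
#' between two members is `(1 - r)^2 + r^2 / 3` (both unmutated, or both
#' mutated to the same base).
#'
#' @param ancestorLength length of the family ancestor.
#' @param nMembers number of members to generate.
#' @param mutationRate per-site substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @param familyName family label attached to all members.
#' @param oracle a [FoldOracle-class].
#' @return an [RnaRecordSet-class] of `nMembers` records.
#' @export
generateFamily <- function(ancestorLength, nMembers, mutationRate, seed = 1L,
                           familyName = "fam1", oracle = FoldOracle()) {
  if (mutationRate < 0 || mutationRate >= 1)
    stop("mutationRate must be in [0, 1)")
  withSeed(seed, {
    ancestor <- randomSequence(ancestorLength)
    seqs <- vapply(seq_len(nMembers),
                   function(i) mutateSequence(ancestor, mutationRate), "")
    RnaRecordSet(id = sprintf("%s_m%03d", familyName, seq_len(nMembers)),
                 sequence = seqs, family = familyName, cluster = NA_character_,
                 pairs = lapply(seqs, nussinovFold, oracle = oracle))
  })
}

#' Generate a synthetic corpus with family and cluster structure
#'
#' Families get disjoint random ancestors (conditioned on fold stability
#' when `ancestorStability > 0`, emulating within-family structure
#' conservation) and sizes proportional to the configured shares
#' (largest-remainder rounding). Within a family,
#' "primary" members are substitution mutants of the ancestor at the
#' intra-family rate; the remaining records are near-duplicates (rate
#' 0.01 mutants) of cycling primaries, emulating the redundancy clusters
#' of curated RNA corpora. Every record is folded by the Nussinov oracle
#' and labelled with its family and its cluster (the primary it descends
#' from). Byte-identical output under the same configuration.
#'
#' @param config a [CorpusConfig-class].
#' @param oracle a [FoldOracle-class].
#' @return an [RnaRecordSet-class] of `config@nRecords` records.
#' @export
generateCorpus <- function(config, oracle = FoldOracle()) {
  methods::validObject(config)
  shares <- config@familyShares
  n <- config@nRecords
  sizes <- floor(shares * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(shares * n - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  withSeed(config@seed, {
    sets <- lapply(seq_len(config@nFamilies), function(f) {
      fam <- sprintf("fam%d", f)
      nf <- sizes[f]
      if (nf == 0) return(NULL)
      L <- sample(config@lengthRanges[f, 1]:config@lengthRanges[f, 2], 1L)
      ancestor <- sampleStableAncestor(L, config@intraMutationRate,
                                       config@ancestorStability, oracle)
      nPrimary <- max(1L, round(nf / (1 + config@clusterRedundancy)))
      primary <- vapply(seq_len(nPrimary), function(i)
        mutateSequence(ancestor, config@intraMutationRate), "")
      nDup <- nf - nPrimary
      parent <- if (nDup > 0) rep_len(seq_len(nPrimary), nDup) else integer(0)
      dup <- vapply(parent, function(pi) mutateSequence(primary[pi], 0.01), "")
      seqs <- c(primary, dup)
      clus <- sprintf("%s_c%03d", fam, c(seq_len(nPrimary), parent))
      RnaRecordSet(id = sprintf("%s_r%04d", fam, seq_len(nf)),
                   sequence = seqs, family = fam, cluster = clus,
                   pairs = lapply(seqs, nussinovFold, oracle = oracle))
    })
    do.call(c, Filter(Negate(is.null), sets))
  })
}

#' Write a synthetic corpus as dot-bracket plus a families TSV
#'
#' @param x an [RnaRecordSet-class].
#' @param dir output directory (created if needed).
#' @param stem file stem; writes `<stem>.dbn` and `<stem>_families.tsv`.
#' @return the directory, invisibly.
#' @export
writeCorpus <- function(x, dir, stem = "corpus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeRnaRecords(x, file.path(dir, paste0(stem, ".dbn")), "dotbracket")
  utils::write.table(
    data.frame(id = x@id, family = x@family, cluster = x@cluster),
    file.path(dir, paste0(stem, "_families.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a corpus written by [writeCorpus()]
#' @param dir directory containing the corpus files.
#' @param stem file stem.
#' @return an [RnaRecordSet-class] with family and cluster labels.
#' @export
readCorpus <- function(dir, stem = "corpus") {
  x <- readRnaRecords(file.path(dir, paste0(stem, ".dbn")), "dotbracket")
  meta <- utils::read.table(file.path(dir, paste0(stem, "_families.tsv")),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  m <- match(x@id, meta$id)
  x@family <- as.character(meta$family[m])
  x@cluster <- as.character(meta$cluster[m])
  x
}

#' Serialize a CorpusConfig to YAML
#' @param config a [CorpusConfig-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCorpusConfig <- function(config, path) {
  yaml::write_yaml(list(
    n_records = config@nRecords, n_families = config@nFamilies,
    family_shares = config@familyShares,
    length_min = config@lengthRanges[, 1],
    length_max = config@lengthRanges[, 2],
    intra_mutation_rate = config@intraMutationRate,
    cluster_redundancy = config@clusterRedundancy,
    ancestor_stability = config@ancestorStability,
    seed = config@seed), path)
  invisible(path)
}

#' Read a CorpusConfig from YAML
#' @param path file written by [writeCorpusConfig()].
#' @return a [CorpusConfig-class].
#' @export
readCorpusConfig <- function(path) {
  y <- yaml::read_yaml(path)
  CorpusConfig(nRecords = y$n_records, nFamilies = y$n_families,
               familyShares = y$family_shares,
               lengthRanges = cbind(y$length_min, y$length_max),
               intraMutationRate = y$intra_mutation_rate,
               clusterRedundancy = y$cluster_redundancy,
               ancestorStability = if (is.null(y$ancestor_stability)) 0
                                   else y$ancestor_stability,
               seed = y$seed)
}
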