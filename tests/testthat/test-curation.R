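test_that("filterLength is inclusive at the boundary", {
  x <- RnaRecordSet(c("a", "b", "c"),
                    vapply(c(100, 600, 601), function(L)
                      paste(rep("A", L), collapse = ""), ""))
  expect_equal(recordIds(filterLength(x)), c("a", "b"))
  expect_equal(length(filterLength(x[0])), 0L)
  expect_equal(length(filterLength(x[1:2])), 2L)
})

test_that("dedupExact keeps first occurrences and is idempotent", {
  x <- RnaRecordSet(c("a", "b", "c"), c("ACGU", "GGGG", "ACGU"),
                    pairs = list(emptyPairs_(), emptyPairs_(),
                                 cbind(1L, 4L)))
  expect_message(y <- dedupExact(x), "1 duplicate")
  expect_equal(recordIds(y), c("a", "b"))   # first kept despite structure
  expect_equal(recordIds(dedupExact(y)), recordIds(y))
  z <- RnaRecordSet(c("p", "q"), c("AAAA", "CCCC"))
  expect_equal(length(dedupExact(z)), 2L)
})

test_that("greedy clustering groups near-identical sequences", {
  set.seed(5)
  base <- randomRna(50)
  b <- strsplit(base, "")[[1]]
  b[25] <- setdiff(c("A", "C", "G", "U"), b[25])[1]
  mutant <- paste(b, collapse = "")          # single point mutation
  far <- paste(rep(c("A", "C"), 25), collapse = "")
  x <- RnaRecordSet(c("r1", "r2", "r3"), c(base, mutant, far))
  cs <- clusterGreedy(x)
  m <- clusterMembership(cs)
  expect_equal(m$representative_id[m$member_id == "r2"],
               m$representative_id[m$member_id == "r1"])  # identity 49/50
  expect_equal(length(clusterRepresentatives(cs)), 2L)
})

test_that("identical sequences cluster; dissimilar ones found singletons", {
  x <- RnaRecordSet(c("a", "b", "c"),
                    c("GGGGGAAAAACCCCCUUUUU", "GGGGGAAAAACCCCCUUUUU",
                      paste(rep("AC", 10), collapse = "")))
  cs <- clusterGreedy(x)
  expect_equal(length(clusterRepresentatives(cs)), 2L)
  set.seed(4)
  y <- RnaRecordSet(sprintf("d%d", 1:8), replicate(8, randomRna(40)))
  singles <- clusterGreedy(y, identityCutoff = 0.999)
  expect_equal(length(clusterRepresentatives(singles)), length(y))
  expect_error(clusterGreedy(y, identityCutoff = 1.5), "identityCutoff")
})

test_that("every cluster member aligns to its representative at the cutoff", {
  corp <- tinyCorpus(30L, seed = 11L)
  cs <- clusterGreedy(corp, identityCutoff = 0.8)
  m <- clusterMembership(cs)
  seqs <- rnaSequences(corp)
  for (r in seq_len(nrow(m))) {
    if (m$member_id[r] == m$representative_id[r]) next
    idy <- alignIdentity(seqs[[m$member_id[r]]],
                         seqs[[m$representative_id[r]]],
                         denom = "shorter")$identity
    expect_gte(idy, 0.8)
  }
})

test_that("representatives form the greedy length-order solution", {
  # brute-force re-run of the greedy contract on a small instance
  corp <- tinyCorpus(10L, seed = 21L)
  cs <- clusterGreedy(corp, identityCutoff = 0.8)
  seqs <- rnaSequences(corp)
  ord <- order(-nchar(seqs), recordIds(corp))
  ids <- recordIds(corp)[ord]
  reps <- character(0)
  expectRep <- character(0)
  for (id in ids) {
    hit <- NA_character_
    for (r in reps) {
      shared <- any(kmers_(seqs[[id]]) %in% kmers_(seqs[[r]]))
      if (shared &&
          alignIdentity(seqs[[id]], seqs[[r]],
                        denom = "shorter")$identity >= 0.8) {
        hit <- r; break
      }
    }
    if (is.na(hit)) { reps <- c(reps, id); hit <- id }
    expectRep[id] <- hit
  }
  m <- clusterMembership(cs)
  expect_equal(expectRep[m$member_id], setNames(m$representative_id,
                                                m$member_id))
})

test_that("filterCrossSet removes test records similar to training", {
  set.seed(9)
  base <- randomRna(60)
  b <- strsplit(base, "")[[1]]
  idx <- sample(60, 9)                      # ~85% identity mutant
  for (i in idx) b[i] <- setdiff(c("A", "C", "G", "U"), b[i])[1]
  near <- paste(b, collapse = "")
  train <- RnaRecordSet("t1", base)
  test <- RnaRecordSet(c("s1", "s2", "s3"),
                       c(base, near, paste(rep("GA", 30), collapse = "")))
  expect_message(kept <- filterCrossSet(test, train), "removed 2")
  expect_equal(recordIds(kept), "s3")
  # post-condition: all remaining identities below the cutoff
  for (id in recordIds(kept))
    expect_lt(alignIdentity(rnaSequences(kept)[[id]], base,
                            denom = "shorter")$identity, 0.8)
})

test_that("makeSplit honours ratios, determinism and family holdout", {
  corp <- generateCorpus(CorpusConfig(
    nRecords = 100L, nFamilies = 3L, familyShares = c(0.5, 0.3, 0.2),
    lengthRanges = cbind(rep(20, 3), rep(30, 3)),
    intraMutationRate = 0.1, clusterRedundancy = 0.5, seed = 8L))
  sp <- makeSplit(corp, "cross_sequence", seed = 4L)
  expect_equal(length(sp@tr), 70L)
  expect_equal(length(sp@vl), 15L)
  expect_equal(length(sp@ts), 15L)
  expect_equal(sort(c(sp@tr, sp@vl, sp@ts)), sort(recordIds(corp)))
  sp2 <- makeSplit(corp, "cross_sequence", seed = 4L)
  expect_identical(sp@tr, sp2@tr)
  expect_identical(sp@ts, sp2@ts)
  fam <- makeSplit(corp, "cross_family", holdoutFamily = "fam2", seed = 4L)
  expect_setequal(fam@ts, recordIds(corp)[families(corp) == "fam2"])
  expect_false(any(families(corp)[fam@tr] == "fam2"))
  expect_false(any(families(corp)[fam@vl] == "fam2"))
  expect_error(makeSplit(corp, "cross_family", holdoutFamily = "nope"),
               "unknown family")
  expect_error(makeSplit(corp, "cross_sequence", ratios = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("SplitSpec and ClusterSet serializations round trip", {
  corp <- tinyCorpus(12L, seed = 31L)
  sp <- makeSplit(corp, "cross_sequence", seed = 7L)
  f <- withr::local_tempfile(fileext = ".json")
  writeSplitSpec(sp, f)
  back <- readSplitSpec(f)
  expect_identical(back@tr, sp@tr)
  expect_identical(back@level, sp@level)
  expect_identical(back@seed, sp@seed)
  cs <- clusterGreedy(corp)
  g <- withr::local_tempfile(fileext = ".tsv")
  writeClusterSet(cs, g)
  tab <- read.table(g, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), length(corp))
})
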