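test_that("dot-bracket parsing matches bracket structure", {
  f <- withr::local_tempfile(fileext = ".dbn")
  writeLines(c(">hairpin", "GGGAAAACCC", "(((....)))",
               ">open", "AC", ".."), f)
  x <- readRnaRecords(f, "dotbracket")
  expect_equal(length(x), 2L)
  expect_equal(basePairs(x)[["hairpin"]],
               cbind(i = 1:3, j = c(10L, 9L, 8L)))
  expect_equal(nrow(basePairs(x)[["open"]]), 0L)
})

test_that("all four bracket tiers are parsed and T maps to U", {
  f <- withr::local_tempfile(fileext = ".dbn")
  writeLines(c(">pk", "GGTTAAAACCAA", "(([[..))..]]"), f)
  x <- readRnaRecords(f, "dotbracket")
  expect_equal(rnaSequences(x)[["pk"]], "GGUUAAAACCAA")
  expect_equal(nrow(basePairs(x)[["pk"]]), 4L)
})

test_that("unbalanced brackets raise an error naming the line", {
  f <- withr::local_tempfile(fileext = ".dbn")
  writeLines(c(">bad", "GGGAAAACCC", "(((.....))"), f)
  expect_error(readRnaRecords(f, "dotbracket"), "unbalanced.*line 3")
})

test_that("a CT file yields the identical record as its dot-bracket form", {
  db <- withr::local_tempfile(fileext = ".dbn")
  writeLines(c(">hairpin", "GGGAAAACCC", "(((....)))"), db)
  ref <- readRnaRecords(db, "dotbracket")
  ct <- withr::local_tempfile(fileext = ".ct")
  writeRnaRecords(ref, ct, "ct")
  again <- readRnaRecords(ct, "ct")
  expect_equal(rnaSequences(again)[[1]], rnaSequences(ref)[[1]])
  expect_equal(basePairs(again)[[1]], basePairs(ref)[[1]])
})

test_that("non-monotone CT indices raise an error naming the line", {
  f <- withr::local_tempfile(fileext = ".ct")
  writeLines(c("3 bad",
               "1 G 0 2 0 1",
               "3 G 2 4 0 3"), f)
  expect_error(readRnaRecords(f, "ct"), "line 3.*non-monotone")
})

test_that("multiplet partner assignments keep the first-listed partner", {
  f <- withr::local_tempfile(fileext = ".bpseq")
  # positions 1 and 2 both claim position 8
  writeLines(c("# multi",
               sprintf("%d %s %d", 1:8, strsplit("GGAAAACC", "")[[1]],
                       c(8, 8, 0, 0, 0, 0, 0, 1))), f)
  expect_message(x <- readRnaRecords(f, "bpseq"), "multiplet")
  expect_equal(basePairs(x)[[1]], cbind(i = 1L, j = 8L))
})

test_that("read-write-read round trips are the identity for every format", {
  corp <- tinyCorpus(10L)
  for (fmt in c("dotbracket", "ct", "bpseq")) {
    f <- withr::local_tempfile()
    writeRnaRecords(corp, f, fmt)
    back <- readRnaRecords(f, fmt)
    expect_equal(recordIds(back), recordIds(corp))
    expect_equal(unname(rnaSequences(back)), unname(rnaSequences(corp)))
    expect_equal(unname(basePairs(back)), unname(basePairs(corp)),
                 info = fmt)
    # second round trip is bit-exact
    f2 <- withr::local_tempfile()
    writeRnaRecords(back, f2, fmt)
    expect_identical(readLines(f), readLines(f2))
  }
  f <- withr::local_tempfile(fileext = ".fa")
  writeRnaRecords(corp, f, "fasta")
  back <- readRnaRecords(f, "fasta")
  expect_equal(unname(rnaSequences(back)), unname(rnaSequences(corp)))
  expect_true(all(vapply(basePairs(back), nrow, 1L) == 0L))
})

test_that("pairsToMatrix builds symmetric binary matrices", {
  x <- RnaRecordSet("a", "ACGU", pairs = list(emptyPairs_()))
  expect_equal(pairsToMatrix(x), matrix(0, 4, 4))
  y <- RnaRecordSet("b", "GAAC", pairs = list(cbind(1L, 4L)))
  M <- pairsToMatrix(y)
  expect_equal(sum(M), 2)
  expect_equal(M[1, 4], 1); expect_equal(M[4, 1], 1)
  hp <- RnaRecordSet("h", "GGGAAAACCC",
                     pairs = list(cbind(1:3, c(10L, 9L, 8L))))
  Mh <- pairsToMatrix(hp)
  expect_equal(sum(Mh), 6)          # 2 cells per pair
  expect_identical(Mh, t(Mh))
  expect_true(all(diag(Mh) == 0))
  expect_equal(matrixToPairs(Mh), basePairs(hp)[[1]])
})

test_that("removeNonCanonical keeps exactly AU/GC/GU and is idempotent", {
  x <- RnaRecordSet("a", "ACGUGUNA",
                    pairs = list(rbind(c(1L, 2L),   # A-C not canonical
                                       c(3L, 4L),   # G-U wobble
                                       c(5L, 6L),   # G-U wobble
                                       c(7L, 8L)))) # N-A ambiguous
  y <- removeNonCanonical(x)
  expect_equal(basePairs(y)[[1]], cbind(i = c(3L, 5L), j = c(4L, 6L)))
  expect_equal(basePairs(removeNonCanonical(y)), basePairs(y))
  z <- RnaRecordSet("b", "GCGUAU",
                    pairs = list(rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L))))
  expect_equal(nrow(basePairs(removeNonCanonical(z))[[1]]), 3L)
})

test_that("removePseudoknots returns a maximum nested subset", {
  nested <- RnaRecordSet("a", paste(rep("A", 10), collapse = ""),
                         pairs = list(rbind(c(1L, 10L), c(2L, 9L))))
  expect_equal(basePairs(removePseudoknots(nested))[[1]],
               basePairs(nested)[[1]])
  crossing <- RnaRecordSet("b", paste(rep("A", 9), collapse = ""),
                           pairs = list(rbind(c(1L, 6L), c(4L, 9L))))
  expect_equal(nrow(basePairs(removePseudoknots(crossing))[[1]]), 1L)
  mixed <- RnaRecordSet("c", paste(rep("A", 13), collapse = ""),
                        pairs = list(rbind(c(1L, 10L), c(2L, 9L), c(5L, 13L))))
  expect_equal(basePairs(removePseudoknots(mixed))[[1]],
               cbind(i = 1:2, j = c(10L, 9L)))
})

test_that("pseudoknot removal equals the brute-force maximum on random pair sets", {
  set.seed(41)
  for (rep in 1:25) {
    L <- sample(15:30, 1)
    k <- sample(2:min(8, L %/% 2), 1)
    p <- randomPairSet(L, k)
    x <- RnaRecordSet("r", paste(rep("A", L), collapse = ""), pairs = list(p))
    kept <- basePairs(removePseudoknots(x))[[1]]
    expect_false(crossingPairs(kept))
    expect_equal(nrow(kept), bruteMaxNestedSize(normalizePairs_(p)))
  }
})
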