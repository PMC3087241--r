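# Sequence data model: IUPAC algebra, degenerate-aware matching, FASTA and
# group-map IO, pairwise identity.

test_that("degenerate expansion follows the IUPAC definitions", {
  expect_identical(expandDegenerate("MAGT"), c("AAGT", "CAGT"))
  expect_identical(expandDegenerate("ACGT"), "ACGT")
  # two two-fold degenerate positions -> 2 x 2 expansions
  f11 <- "MAGTGATATGGACTAWGTGG"
  expect_length(expandDegenerate(f11), 4L)
  expect_identical(expandDegenerate(f11), bfExpand(f11))
  expect_equal(oligoDegeneracy(f11), 4L)
  expect_error(expandDegenerate("ACXT"), "position 3")
  expect_error(degenerateOligo("p", "AC-T"), "position 3")
})

test_that("reverse complement is IUPAC-aware and an involution", {
  expect_identical(revComp("ACGT"), "ACGT")
  expect_identical(revComp("MAGTGATATGGACTAWGTGG"), "CCACWTAGTCCATATCACTK")
  set.seed(11)
  for (i in 1:25) {
    x <- randDegenerate(sample(8:30, 1), nDeg = sample(0:3, 1))
    expect_identical(revComp(revComp(x)), x)
    expect_identical(revComp(x), bfRevComp(x))
    # expansion commutes with reverse complementation
    expect_setequal(expandDegenerate(revComp(x)),
                    vapply(expandDegenerate(x), bfRevComp, character(1)))
  }
})

test_that("mismatch counting matches exhaustive expansion", {
  expect_equal(mismatchCount("CCACCAATCAGCGTTGATA",
                             "CCACCAATCAGCAGTGATA"), 2L)
  expect_equal(mismatchCount("M", "A"), 0L)
  x <- randSeq(20)
  expect_equal(mismatchCount(x, x), 0L)
  expect_error(mismatchCount("ACG", "ACGT"), "equal length")
  set.seed(21)
  for (i in 1:60) {
    o <- randDegenerate(sample(4:12, 1), nDeg = sample(0:3, 1))
    w <- randSeq(nchar(o))
    expect_equal(mismatchCount(o, w), bfMismatch(o, w))
  }
})

test_that("window scan equals exhaustive enumeration with stated tie-breaks", {
  hit <- minMismatches("ACGT", "TTACGTTT")
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$start, 2L)
  expect_equal(hit$strand, "given")
  # ACGT is its own reverse complement: both-strand scan reports the
  # given strand by the tie-break
  hit2 <- minMismatches("ACGT", "TTACGTTT", strands = "both")
  expect_equal(hit2[c("mismatches", "start", "strand")],
               list(mismatches = 0L, start = 2L, strand = "given"))
  expect_error(minMismatches("ACGTACGT", "ACG"), "shorter")
  set.seed(31)
  for (i in 1:40) {
    o <- randDegenerate(sample(5:10, 1), nDeg = sample(0:2, 1))
    t <- randSeq(sample(nchar(o):60, 1))
    got <- minMismatches(o, t, strands = "both")
    want <- bfMinMismatch(o, t, both = TRUE)
    expect_equal(got$mismatches, want$mm)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
  }
})

test_that("a planted approximate match is found by the scan", {
  set.seed(41)
  for (i in 1:10) {
    probe <- randSeq(20)
    bg <- randSeq(300)
    pos <- sample(0:(300 - 20), 1)
    mutated <- strsplit(probe, "")[[1]]
    j <- sample.int(20, 1)
    mutated[j] <- setdiff(c("A", "C", "G", "T"), mutated[j])[1]
    target <- paste0(substr(bg, 1, pos), paste(mutated, collapse = ""),
                     substr(bg, pos + 21, 300))
    got <- minMismatches(probe, target)
    want <- bfMinMismatch(probe, target)
    expect_equal(got$mismatches, want$mm)
    expect_equal(got$start, want$start)
  }
})

test_that("FASTA IO takes first-token ids and round-trips losslessly", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT"), f)
  expect_identical(readFasta(f), c(s1 = "ACGT"))
  writeLines(c(">AM110086 Polynucleobacter", "ACGTACGT"), f)
  expect_identical(names(readFasta(f)), "AM110086")
  # round trip
  seqs <- c(a = randSeq(80), b = randSeq(120))
  writeFasta(seqs, f)
  expect_identical(readFasta(f), seqs)
  # empty file is an empty result, not an error
  writeLines(character(0), f)
  expect_length(readFasta(f), 0L)
  # sequence before header names the line
  writeLines(c("ACGT", ">s1", "ACGT"), f)
  expect_error(readFasta(f), "line 1")
})

test_that("collection loading builds the group index and checks ids", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  gm <- withr::local_tempfile(fileext = ".tsv")
  writeFasta(c(s1 = randSeq(50), s2 = randSeq(50), s3 = randSeq(50)), fa)
  writeLines(c("strain_id\tgroups", "s1\tF15", "s2\tF15,F15-1"), gm)
  coll <- loadCollection(fa, gm)
  expect_identical(groupIndex(coll),
                   list(F15 = c("s1", "s2"), `F15-1` = "s2"))
  expect_identical(coll@groups[["s3"]], character(0))
  # empty map -> all ungrouped
  writeLines("strain_id\tgroups", gm)
  coll2 <- loadCollection(fa, gm)
  expect_length(groupNames(coll2), 0L)
  # unknown id in the map is an error naming it
  writeLines(c("strain_id\tgroups", "s9\tF1"), gm)
  expect_error(loadCollection(fa, gm), "s9")
  # duplicate id in the map
  writeLines(c("strain_id\tgroups", "s1\tF1", "s1\tF2"), gm)
  expect_error(loadCollection(fa, gm), "duplicate")
})

test_that("pairwise identity is a symmetric global-alignment percentage", {
  expect_equal(pairwiseIdentity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(pairwiseIdentity("AAAA", "AAAT"), 75)
  set.seed(51)
  for (i in 1:10) {
    a <- randSeq(sample(30:60, 1))
    b <- randSeq(sample(30:60, 1))
    expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
  }
  expect_error(pairwiseIdentity("", "ACGT"), "non-empty")
})
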