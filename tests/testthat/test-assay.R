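# In silico PCR (primer sites, amplification, nesting) and the RLBH
# signal simulation.

.refP <- referencePrimers()

test_that("primer sites honour degeneracy, budget and the 3' clamp", {
  set.seed(81)
  # Y = C/T: the concrete C variant is one exact site on the given strand
  r5 <- "AACGAGCACCATTGCTAGY"
  target <- paste0(randSeq(40), "AACGAGCACCATTGCTAGC", randSeq(40))
  sites <- findPrimerSites(target, r5, maxMm = 0, clamp = 3)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 40L)
  expect_equal(sites$mismatches, 0L)
  expect_equal(sites$strand, "+")
  # the same site is found on the minus strand of the reverse-complemented
  # template
  sitesRc <- findPrimerSites(revComp(target), r5, maxMm = 0, clamp = 3)
  expect_equal(sitesRc$strand, "-")
  # absent primer -> empty
  expect_equal(nrow(findPrimerSites(randSeq(60), "GGGGGGGGCCCCCCCC",
                                    maxMm = 0, clamp = 3)), 0L)
  # a mismatch inside the 3' clamp rejects the site even within budget
  primer <- randSeq(20)
  tmpl <- paste0(randSeq(30), primer, randSeq(30))
  mutated <- strsplit(primer, "")[[1]]
  mutated[20] <- setdiff(c("A", "C", "G", "T"), mutated[20])[1]
  tmplClamp <- paste0(randSeq(30), paste(mutated, collapse = ""), randSeq(30))
  expect_gt(nrow(findPrimerSites(tmpl, primer, maxMm = 1, clamp = 3)), 0L)
  hitsAt30 <- findPrimerSites(tmplClamp, primer, maxMm = 1, clamp = 3)
  expect_false(30 %in% hitsAt30$start)
})

test_that("amplification spans forward start to reverse-site end", {
  set.seed(82)
  fwd <- randSeq(20)
  rev <- randSeq(19)
  # forward site at 10; reverse-complement site occupying [181, 200)
  tmpl <- paste0(randSeq(10), fwd, randSeq(151), revComp(rev), randSeq(50))
  pair <- primerPair(fwd, rev, maxMismatches = 0, clamp = 3)
  amp <- amplify(c(t1 = tmpl), pair)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 10L)
  expect_equal(amp$end, 200L)
  expect_equal(amp$length, 190L)
  expect_identical(amp$sequence, substr(tmpl, 11, 200))
  # a template lacking the forward site yields nothing
  expect_equal(nrow(amplify(c(t2 = paste0(randSeq(150), revComp(rev),
                                          randSeq(30))), pair)), 0L)
  # two forward sites upstream of one reverse site -> two amplicons
  tmpl2 <- paste0(randSeq(5), fwd, randSeq(40), fwd, randSeq(80),
                  revComp(rev), randSeq(20))
  amp2 <- amplify(c(t3 = tmpl2), pair)
  expect_equal(nrow(amp2), 2L)
  expect_error(amplify(c(t1 = tmpl), pair, lengthBounds = c(500, 100)),
               "inverted")
})

test_that("nested PCR is gated by the outer pair and stays inside it", {
  set.seed(83)
  oF <- randSeq(18); oR <- randSeq(18)
  iF <- randSeq(20); iR <- randSeq(19)
  core <- randSeq(150)
  tmpl <- paste0(randSeq(8), oF, randSeq(12), iF, core, revComp(iR),
                 randSeq(12), revComp(oR), randSeq(9))
  outer <- primerPair(oF, oR, maxMismatches = 0, clamp = 3)
  inner <- primerPair(iF, iR, maxMismatches = 0, clamp = 3)
  nested <- nestedAmplify(c(t1 = tmpl), outer, inner)
  expect_equal(nrow(nested), 1L)
  expect_identical(nested$round, "nested")
  single <- amplify(c(t1 = tmpl), outer)
  expect_gte(nested$start, single$start)
  expect_lte(nested$end, single$end)
  expect_identical(nested$sequence,
                   substr(tmpl, nested$start + 1, nested$end))
  # inner sites without outer sites -> empty (outer gate)
  tmplInnerOnly <- paste0(randSeq(20), iF, core, revComp(iR), randSeq(20))
  expect_equal(nrow(nestedAmplify(c(t2 = tmplInnerOnly), outer, inner)), 0L)
  # outer only -> empty after the inner round
  tmplOuterOnly <- paste0(randSeq(8), oF, randSeq(180), revComp(oR),
                          randSeq(9))
  expect_equal(nrow(nestedAmplify(c(t3 = tmplOuterOnly), outer, inner)), 0L)
})

test_that("generated strains amplify with the reference nested scheme", {
  gen <- generateCollection(collectionSpec(nGroups = 2, strainsPerGroup = 3,
                                           markerLength = 200), seed = 9)
  amp <- nestedAmplify(gen$collection, .refP$outer, .refP$inner)
  expect_equal(nrow(amp), nStrains(gen$collection))
  expect_true(all(amp$round == "nested"))
})

test_that("hybridization detects exactly the pooled groups", {
  gen <- generateCollection(collectionSpec(nGroups = 3, strainsPerGroup = 4,
                                           markerLength = 250), seed = 10)
  coll <- gen$collection
  panel <- designPanel(coll)
  model <- hybridizationModel()
  # pure culture: positive exactly for the strain's group probe
  s <- groupMembers(coll, "G02")[1]
  pool <- data.frame(strain_id = s, abundance = 1)
  row <- hybridize(panel, pool, coll, model, .refP$inner)
  expect_identical(names(which(row$class != "none")), "G02")
  # empty pool: all none
  empty <- hybridize(panel, pool[0, ], coll, model, .refP$inner)
  expect_true(all(empty$class == "none"))
  # order invariance and abundance monotonicity
  pool2 <- data.frame(strain_id = c(groupMembers(coll, "G01")[1],
                                    groupMembers(coll, "G03")[2]),
                      abundance = c(0.3, 0.7))
  a <- hybridize(panel, pool2, coll, model, .refP$inner)
  b <- hybridize(panel, pool2[2:1, ], coll, model, .refP$inner)
  expect_equal(a$signal, b$signal)
  pool3 <- pool2
  pool3$abundance[1] <- pool3$abundance[1] * 2
  c2 <- hybridize(panel, pool3, coll, model, .refP$inner)
  # doubling a member's (pre-normalization) abundance never lowers its
  # probe's signal
  expect_gte(c2$signal[["G01"]], a$signal[["G01"]])
})

test_that("signal classes follow the two cut points and the floor", {
  m <- hybridizationModel(detectionFloor = 1e-3,
                          thresholds = c(1e-2, 1e-1))
  expect_identical(unname(rlbh:::.classify(c(0, 5e-4, 5e-3, 5e-2, 0.5), m)),
                   c("none", "none", "weak", "average", "very_strong"))
  expect_error(hybridizationModel(thresholds = c(0.1, 0.1)), "increasing")
  expect_error(hybridizationModel(gains = 0), "gains")
})

test_that("binarization rules and idempotence", {
  cls <- matrix(c("none", "weak", "very_strong",
                  "average", "none", "weak"), nrow = 2, byrow = TRUE,
                dimnames = list(c("h1", "h2"), c("p1", "p2", "p3")))
  dm <- new("DetectionMatrix",
            signal = matrix(c(0, 0.005, 0.5, 0.05, 0, 0.005), nrow = 2,
                            byrow = TRUE, dimnames = dimnames(cls)),
            classes = cls, metadata = list())
  expect_identical(unname(binarize(dm)[1, ]), c(0L, 1L, 1L))
  expect_identical(unname(binarize(dm, "exclude_weak")[1, ]), c(0L, 0L, 1L))
  b <- binarize(dm)
  expect_identical(binarize(b), b)
  expect_error(binarize(dm, "nonsense"))
})

test_that("a full pool set round-trips through the detection matrix IO", {
  gen <- generateCollection(collectionSpec(nGroups = 2, strainsPerGroup = 3,
                                           markerLength = 200), seed = 14)
  coll <- gen$collection
  panel <- designPanel(coll)
  pools <- data.frame(
    habitat_id = c("h1", "h1", "h2"),
    strain_id = c(groupMembers(coll, "G01")[1], groupMembers(coll, "G02")[1],
                  groupMembers(coll, "G02")[2]),
    abundance = c(0.5, 0.5, 1))
  dm <- hybridizePools(panel, pools, coll, hybridizationModel(), .refP$inner)
  expect_equal(dim(signalMatrix(dm)), c(2L, 2L))
  expect_identical(unname(binarize(dm)["h1", ]), c(1L, 1L))
  expect_identical(unname(binarize(dm)["h2", ]), c(0L, 1L))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDetectionMatrix(dm, f)
  back <- readDetectionMatrix(f)
  expect_identical(classMatrix(back), classMatrix(dm))
  expect_identical(binarize(back), binarize(dm))
  expect_identical(readBinaryMatrix(paste0(f, ".binary.tsv")), binarize(dm))
})
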