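# Probe design: candidate enumeration, specificity scoring, panel
# selection and in silico validation.

# small helper: collection of two groups built from explicit sequences
.twoGroups <- function(g1, g2) {
  seqs <- c(setNames(g1, sprintf("A_s%d", seq_along(g1))),
            setNames(g2, sprintf("B_s%d", seq_along(g2))))
  groups <- c(setNames(rep(list("A"), length(g1)),
                       sprintf("A_s%d", seq_along(g1))),
              setNames(rep(list("B"), length(g2)),
                       sprintf("B_s%d", seq_along(g2))))
  strainCollection(seqs, groups)
}

test_that("a shared unique window yields a perfect concrete candidate", {
  set.seed(71)
  bg <- randSeq(200)
  site <- randSeq(20)
  withSite <- paste0(substr(bg, 1, 90), site, substr(bg, 111, 200))
  coll <- .twoGroups(rep(withSite, 5), rep(bg, 4))
  cands <- enumerateCandidates(coll, "A")
  expect_gt(nrow(cands), 0)
  top <- cands[1, ]
  expect_equal(top$coverage, 1)
  expect_equal(top$degeneracy, 1L)
  expect_gte(top$nontarget_min_mm, 2L)
  # the top candidate overlaps the planted site
  ov <- min(top$start + top$length, 110) - max(top$start, 90)
  expect_gt(ov, 0)
})

test_that("a within-group SNP in the only feasible window emits one IUPAC code", {
  for (seed in 1:5) {
    fix <- generateSnpCollection(seed = seed)
    cands <- enumerateCandidates(fix$collection, fix$group)
    expect_gt(nrow(cands), 0)
    top <- cands[1, ]
    expect_equal(top$n_degenerate, 1L)
    expect_equal(top$degeneracy, 2L)
    # the degenerate column sits at the SNP position
    snpInWindow <- fix$snpPosition - top$start
    chars <- strsplit(top$sequence, "")[[1]]
    expect_true(chars[snpInWindow + 1] %in%
                  c("M", "R", "W", "S", "Y", "K"))
    # and it covers both alleles: every group member perfect-matches
    expect_equal(top$coverage, 1)
  }
})

test_that("a group indistinguishable from non-targets yields no candidate", {
  set.seed(72)
  bg <- randSeq(150)
  coll <- .twoGroups(rep(bg, 3), rep(bg, 3))
  expect_equal(nrow(enumerateCandidates(coll, "A")), 0L)
  expect_error(enumerateCandidates(coll, "Z"), "unknown group")
})

test_that("emitted candidates satisfy every hard constraint post hoc", {
  for (seed in c(3, 9)) {
    gen <- generateCollection(collectionSpec(nGroups = 3, strainsPerGroup = 5,
                                             markerLength = 200), seed = seed)
    cons <- designConstraints()
    for (g in groupNames(gen$collection)) {
      cc <- enumerateCandidates(gen$collection, g, cons)
      if (!nrow(cc)) next
      expect_true(all(cc$coverage >= cons$minGroupCoverage))
      expect_true(all(cc$nontarget_min_mm >= cons$minNontargetMismatches))
      expect_true(all(cc$n_degenerate <= cons$maxDegeneratePositions))
      expect_true(all(cc$length >= cons$lengthRange[1] &
                      cc$length <= cons$lengthRange[2]))
      expect_false(any(duplicated(cc$sequence)))
    }
  }
})

test_that("stored specificity and coverage reproduce under the exhaustive oracle", {
  gen <- generateCollection(collectionSpec(nGroups = 2, strainsPerGroup = 3,
                                           markerLength = 120,
                                           primerFlanks = FALSE), seed = 8)
  coll <- gen$collection
  cc <- enumerateCandidates(coll, "G01")
  expect_gt(nrow(cc), 0)
  seqs <- strainSeqs(coll)
  nontargets <- groupMembers(coll, "G02")
  members <- groupMembers(coll, "G01")
  for (i in unique(c(1L, nrow(cc) %/% 2L, nrow(cc)))) {
    cand <- cc$sequence[i]
    # brute-force both-strand scan over every non-target strain
    bfMin <- min(vapply(nontargets, function(s)
      bfMinMismatch(cand, seqs[[s]], both = TRUE)$mm, numeric(1)))
    expect_equal(cc$nontarget_min_mm[i], bfMin)
    # coverage: fraction of members perfect-matched
    bfCov <- mean(vapply(members, function(s)
      bfMinMismatch(cand, seqs[[s]], both = TRUE)$mm == 0, logical(1)))
    expect_equal(cc$coverage[i], bfCov)
    # scoreSpecificity agrees strain by strain with the oracle
    sp <- scoreSpecificity(cand, coll, "G01")
    for (s in c(members[1], nontargets[1]))
      expect_equal(unname(sp$per_strain[s]),
                   bfMinMismatch(cand, seqs[[s]], both = TRUE)$mm)
  }
})

test_that("specificity is invariant under reverse-complementing a strain", {
  gen <- generateCollection(collectionSpec(nGroups = 2, strainsPerGroup = 3,
                                           markerLength = 120,
                                           primerFlanks = FALSE), seed = 12)
  coll <- gen$collection
  cand <- enumerateCandidates(coll, "G01")$sequence[1]
  sp1 <- scoreSpecificity(cand, coll, "G01")
  flipped <- strainSeqs(coll)
  victim <- groupMembers(coll, "G02")[1]
  flipped[[victim]] <- revComp(flipped[[victim]])
  coll2 <- strainCollection(flipped, coll@groups)
  sp2 <- scoreSpecificity(cand, coll2, "G01")
  expect_identical(sp1$per_strain, sp2$per_strain)
})

test_that("relaxing the non-target floor never loses candidates", {
  for (seed in c(2, 6, 13)) {
    gen <- generateCollection(collectionSpec(nGroups = 3, strainsPerGroup = 4,
                                             markerLength = 150), seed = seed)
    for (g in groupNames(gen$collection)) {
      n2 <- nrow(enumerateCandidates(gen$collection, g,
                                     designConstraints(minNontargetMismatches = 2)))
      n1 <- nrow(enumerateCandidates(gen$collection, g,
                                     designConstraints(minNontargetMismatches = 1)))
      expect_gte(n1, n2)
    }
  }
})

test_that("panel design reports coverage, uncovered strains and infeasible groups", {
  set.seed(73)
  gen <- generateCollection(collectionSpec(nGroups = 4, strainsPerGroup = 4,
                                           markerLength = 250), seed = 4)
  panel <- designPanel(gen$collection)
  expect_equal(nrow(panel@probes), 4L)
  expect_equal(panel@strainCoverage, 1.0)
  expect_length(panel@uncoveredStrains, 0L)
  expect_false(anyDuplicated(panel@probes$probe) > 0)

  # an infeasible group (indistinguishable twin backbones) is reported
  bg <- randSeq(150); other <- randSeq(150)
  seqs <- c(a1 = bg, a2 = bg, b1 = bg, b2 = bg, c1 = other, c2 = other)
  coll <- strainCollection(seqs, list(a1 = "A", a2 = "A", b1 = "B",
                                      b2 = "B", c1 = "C", c2 = "C"))
  panel2 <- designPanel(coll, groups = c("A", "B", "C"))
  expect_setequal(panel2@infeasibleGroups, c("A", "B"))
  expect_equal(nrow(panel2@probes), 1L)
  expect_error(designPanel(coll, groups = character(0)), "non-empty")
})

test_that("validation classifies nested groups without false positives", {
  spec <- collectionSpec(nGroups = 3, strainsPerGroup = 6, markerLength = 300,
    nestedPairs = list(list(parent = "G01", child = "G01c", fraction = 0.5)))
  gen <- generateCollection(spec, seed = 15)
  coll <- gen$collection
  panel <- designPanel(coll, groups = c("G01", "G01c", "G02", "G03"))
  expect_equal(nrow(panel@probes), 4L)
  rep <- validatePanel(panel, coll, perfectMatchOnly = TRUE)
  # classification counts sum to the collection size per probe
  counts <- table(rep@calls$probe)
  expect_true(all(counts == nStrains(coll)))
  expect_true(all(rep@summary$fp == 0))
  expect_true(all(rep@summary$fn == 0))
  # a child strain is positive (true positive) for both probes
  child <- groupMembers(coll, "G01c")[1]
  childCalls <- rep@calls[rep@calls$strain == child &
                          rep@calls$probe %in% c("G01", "G01c"), ]
  expect_true(all(childCalls$classification == "true_positive"))
})

test_that("an empty panel validates to an empty report", {
  gen <- generateCollection(collectionSpec(nGroups = 2, strainsPerGroup = 2,
                                           markerLength = 120), seed = 1)
  empty <- new("ProbePanel",
               probes = designPanel(gen$collection)@probes[0, ],
               strainCoverage = NA_real_, uncoveredStrains = character(0),
               infeasibleGroups = character(0), metadata = list())
  rep <- validatePanel(empty, gen$collection)
  expect_equal(nrow(rep@calls), 0L)
  expect_equal(nrow(rep@summary), 0L)
})
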