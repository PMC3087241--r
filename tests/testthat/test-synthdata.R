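# The synthetic-data generator: determinism, identity bands, environment
# structure, niche model and the end-to-end study bundle.

test_that("generation is byte-deterministic given the seed", {
  g1 <- generateCollection(collectionSpec(nGroups = 3, strainsPerGroup = 4,
                                          markerLength = 200), seed = 5)
  g2 <- generateCollection(collectionSpec(nGroups = 3, strainsPerGroup = 4,
                                          markerLength = 200), seed = 5)
  expect_identical(strainSeqs(g1$collection), strainSeqs(g2$collection))
  expect_identical(g1$sites, g2$sites)
  g3 <- generateCollection(collectionSpec(nGroups = 3, strainsPerGroup = 4,
                                          markerLength = 200), seed = 6)
  expect_false(identical(strainSeqs(g1$collection),
                         strainSeqs(g3$collection)))
})

test_that("identity bands match the intended collection structure", {
  gen <- generateCollection(collectionSpec(), seed = 2)
  seqs <- strainSeqs(gen$collection)
  gi <- groupIndex(gen$collection)
  # within-group identity stays at or above the design band
  set.seed(121)
  for (g in sample(names(gi), 4)) {
    m <- gi[[g]]
    pairs <- t(combn(sample(m, 4), 2))
    for (k in seq_len(nrow(pairs)))
      expect_gte(pairwiseIdentity(seqs[[pairs[k, 1]]], seqs[[pairs[k, 2]]]),
                 98)
  }
  # across groups identity is lower but in the intended range
  across <- c(pairwiseIdentity(seqs[[gi$G01[1]]], seqs[[gi$G05[1]]]),
              pairwiseIdentity(seqs[[gi$G02[1]]], seqs[[gi$G09[1]]]))
  expect_true(all(across < 98))
  expect_true(all(across > 90))
  # zero within-group rate makes members identical
  g0 <- generateCollection(collectionSpec(nGroups = 2, strainsPerGroup = 3,
                                          markerLength = 150,
                                          withinRate = 0), seed = 3)
  m <- groupMembers(g0$collection, "G01")
  ss <- strainSeqs(g0$collection)
  expect_identical(ss[[m[1]]], ss[[m[2]]])
  expect_error(collectionSpec(withinRate = 0.2), "rates")
})

test_that("diagnostic sites are planted, conserved in-group and disjoint", {
  spec <- collectionSpec(nGroups = 4, strainsPerGroup = 5,
                         markerLength = 300,
                         nestedPairs = list(list(parent = "G02",
                                                 child = "G02c",
                                                 fraction = 0.4)))
  gen <- generateCollection(spec, seed = 8)
  sites <- gen$sites
  expect_equal(nrow(sites), 5L)
  # non-overlap
  o <- order(sites$site_start)
  expect_true(all(diff(sites$site_start[o]) >= spec$siteLength))
  # every member carries its group's site verbatim
  seqs <- strainSeqs(gen$collection)
  for (i in seq_len(nrow(sites))) {
    for (m in groupMembers(gen$collection, sites$group[i])) {
      expect_identical(substr(seqs[[m]], sites$site_start[i] + 1,
                              sites$site_start[i] + sites$site_length[i]),
                       sites$site_seq[i])
    }
  }
  # nested child is a strict subset of the parent carrying both labels
  expect_true(all(groupMembers(gen$collection, "G02c") %in%
                  groupMembers(gen$collection, "G02")))
  expect_lt(length(groupMembers(gen$collection, "G02c")),
            length(groupMembers(gen$collection, "G02")))
  expect_error(generateCollection(collectionSpec(nGroups = 30,
                                                 markerLength = 200)),
               "overlap")
})

test_that("habitat environments follow the pH-anchored structure", {
  env <- generateHabitats(habitatSpec(), seed = 1)
  expect_equal(nrow(env), 121L)
  expect_true(all(env$pH >= 3.9 & env$pH <= 8.5))
  expect_gt(cor(env$pH, env$conductivity), 0.5)
  expect_lt(cor(env$pH, env$A250), 0)
  # noise-free conductivity is perfectly rank-correlated with pH
  env0 <- generateHabitats(habitatSpec(condSd = 0), seed = 1)
  expect_equal(cor(env0$pH, env0$conductivity, method = "spearman"), 1)
  # boundary: two habitats still give a valid table
  expect_equal(nrow(generateHabitats(habitatSpec(nHabitats = 2), seed = 1)),
               2L)
  expect_error(habitatSpec(nHabitats = 1), "at least 2")
})

test_that("the Gaussian niche model hits its limiting cases", {
  gen <- generateCollection(collectionSpec(nGroups = 2, strainsPerGroup = 3,
                                           markerLength = 150), seed = 4)
  env <- generateHabitats(habitatSpec(nHabitats = 40), seed = 2)
  # infinite breadth with pmax 1: everything everywhere
  wide <- nicheSpec(c("G01", "G02"), mu = c(5, 8), sigma = 1e6, pmax = 1)
  pg <- generatePools(env, wide, gen$collection, seed = 3)
  expect_true(all(pg$truth == 1L))
  # pmax 0: never present
  off <- nicheSpec(c("G01", "G02"), mu = c(5, 8), sigma = 0.5,
                   pmax = c(0, 0.9))
  pg0 <- generatePools(env, off, gen$collection, seed = 3)
  expect_true(all(pg0$truth[, "G01"] == 0L))
  # pools normalize per habitat
  tot <- tapply(pg$pools$abundance, pg$pools$habitat_id, sum)
  expect_true(all(abs(tot - 1) < 1e-12))
})

test_that("truth-matrix marginals converge to the mean niche probability", {
  gen <- generateCollection(collectionSpec(nGroups = 2, strainsPerGroup = 2,
                                           markerLength = 150), seed = 7)
  env <- generateHabitats(habitatSpec(nHabitats = 2000), seed = 9)
  niches <- nicheSpec(c("G01", "G02"), mu = c(5, 7.5), sigma = 0.8,
                      pmax = 0.9)
  pg <- generatePools(env, niches, gen$collection, seed = 10)
  for (gi in 1:2) {
    p <- niches$pmax[gi] *
      exp(-(env$pH - niches$mu[gi])^2 / (2 * niches$sigma[gi]^2))
    se <- sqrt(sum(p * (1 - p))) / length(p)
    expect_lt(abs(mean(pg$truth[, gi]) - mean(p)), 3 * se + 1e-12)
  }
})

test_that("the study bundle is complete, consistent and reproducible", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  spec <- collectionSpec(nGroups = 3, strainsPerGroup = 3,
                         markerLength = 200)
  hspec <- habitatSpec(nHabitats = 15)
  b1 <- generateStudy(d1, spec, hspec, seed = 42)
  b2 <- generateStudy(d2, spec, hspec, seed = 42)
  for (f in c("strains.fasta", "groups.tsv", "env.tsv", "pools.tsv",
              "truth.tsv", "sites.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_equal(dim(b1$truth), c(15L, 3L))
  # the bundle reloads into the very objects it was generated from
  coll <- loadCollection(b1$paths$fasta, b1$paths$groups)
  expect_identical(strainSeqs(coll), strainSeqs(b1$collection))
  expect_identical(groupIndex(coll), groupIndex(b1$collection))
  env <- readEnvTable(b1$paths$env)
  expect_equal(env$pH, b1$env$pH, tolerance = 1e-9)
})
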