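# Synthetic strain collections, habitat environments and community pools
# with known ground truth.  The generator emulates the statistical
# structure of an intra-subspecies typing study: marker collections whose
# within-group identity stays >= ~98.4% and whose across-collection
# identity reaches down to ~94%, planted group-diagnostic probe sites,
# conserved primer-site flanks so every strain is amplifiable, and habitat
# communities assembled by Gaussian-niche ecotype sorting along a
# pH/conductivity gradient.

# Conserved flanks carrying the assay's primer sites (outer primer, linker,
# inner primer ... marker core ... inner reverse site, linker, outer
# reverse site).  Constant across strains, groups and seeds.
.LEFT_FLANK <- paste0("GTCAGGGAAGAAACACCG", "ATTCGG",
                      "CACACTTATCGGTTGACAATAA")
.RIGHT_FLANK <- paste0("GCTAGCAATGGTGCTCGTT", "TCCGAT",
                       "GTGAACTGAAACATCTAAGTAGC")

#' Reference primer pairs of the simulated assay
#'
#' Outer pair (rRNA-gene anchored) and inner pair (spacer-flank anchored)
#' matching the conserved flanks planted by \code{\link{generateCollection}}.
#'
#' @return list with elements \code{outer} and \code{inner}
#'   (\linkS4class{PrimerPair}s)
#' @export
referencePrimers <- function() {
  oligos <- referenceOligos()
  seqs <- setNames(oligos$sequence, oligos$name)
  list(outer = primerPair(seqs[["PnecC441f"]], seqs[["Poly23Sr"]]),
       inner = primerPair(seqs[["PnecCf-4"]], seqs[["PnecCr-5-BIO"]]))
}

#' Specification of a synthetic strain collection
#'
#' @param nGroups number of (top-level) groups
#' @param strainsPerGroup strains per group
#' @param markerLength length of the variable marker core in nt (the
#'   conserved primer flanks are added on top)
#' @param betweenRate per-site substitution rate from the common ancestor
#'   to each group backbone (default 0.02, tuned so across-collection
#'   identity stays around 94-95\%)
#' @param withinRate per-site substitution rate from the group backbone to
#'   each strain (default 0.002, keeping within-group identity >= ~98.4\%)
#' @param siteLength length of the planted group-diagnostic site
#' @param siteSubstitutions number of evenly spaced substitutions planted
#'   inside each diagnostic site (distinguishes the site from every other
#'   backbone at >= this many mismatches)
#' @param nestedPairs list of \code{list(parent =, child =, fraction =)}
#'   entries: the child group is a subset of the parent's strains carrying
#'   an additional child-diagnostic site
#' @param primerFlanks add the conserved primer-site flanks
#' @param seed default seed used by \code{\link{generateCollection}}
#' @return classed list
#' @export
collectionSpec <- function(nGroups = 10L, strainsPerGroup = 10L,
                           markerLength = 500L, betweenRate = 0.02,
                           withinRate = 0.002, siteLength = 20L,
                           siteSubstitutions = 6L, nestedPairs = list(),
                           primerFlanks = TRUE, seed = 1L) {
  if (betweenRate < 0 || betweenRate > 0.06 ||
      withinRate < 0 || withinRate > 0.06)
    stop("substitution rates must be in [0, 0.06]")
  structure(list(nGroups = as.integer(nGroups),
                 strainsPerGroup = as.integer(strainsPerGroup),
                 markerLength = as.integer(markerLength),
                 betweenRate = betweenRate, withinRate = withinRate,
                 siteLength = as.integer(siteLength),
                 siteSubstitutions = as.integer(siteSubstitutions),
                 nestedPairs = nestedPairs,
                 primerFlanks = isTRUE(primerFlanks),
                 seed = as.integer(seed)),
            class = "CollectionSpec")
}

.randomSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                collapse = "")

# substitute positions of a character vector of bases at `rate`, never
# touching `protected` (1-based positions); substitutions are uniform over
# the three other bases
.mutateBases <- function(bases, rate, protected = integer(0)) {
  hit <- which(runif(length(bases)) < rate)
  hit <- setdiff(hit, protected)
  for (i in hit) bases[i] <- sample(setdiff(.BASES, bases[i]), 1L)
  bases
}

# plant k evenly spaced substitutions inside [start, start+len-1]
.plantSite <- function(bases, start, len, k) {
  pos <- start - 1L + unique(round(seq(1L, len, length.out = k)))
  for (i in pos) bases[i] <- sample(setdiff(.BASES, bases[i]), 1L)
  bases
}

#' Generate a synthetic strain collection with planted diagnostic sites
#'
#' One random backbone per group is derived from a common ancestor by
#' per-group substitutions; each group receives a unique diagnostic site
#' (a window with planted substitutions at fixed, evenly spaced offsets
#' across groups); strains are drawn by within-group substitutions that
#' never touch their own diagnostic site.  Children of nested pairs carry
#' an additional child-diagnostic site and both group labels.
#' Reproducible: the same (spec, seed) yields byte-identical output.
#'
#' @param spec a \code{\link{collectionSpec}}
#' @param seed integer seed (default: the spec's)
#' @return list with \code{collection} (a \linkS4class{StrainCollection})
#'   and \code{sites} (data.frame of ground-truth diagnostic sites with
#'   0-based starts on the final sequences)
#' @export
generateCollection <- function(spec = collectionSpec(), seed = spec$seed) {
  nSites <- spec$nGroups + length(spec$nestedPairs)
  margin <- 10L
  span <- spec$markerLength - 2L * margin - spec$siteLength
  if (nSites < 1L || span < 0L)
    stop("diagnostic sites cannot be placed without overlap")
  offsets <- margin + round(seq(0L, span, length.out = nSites))
  if (nSites > 1L && min(diff(offsets)) < spec$siteLength)
    stop("diagnostic sites cannot be placed without overlap")

  groups <- sprintf("G%02d", seq_len(spec$nGroups))
  childOf <- vapply(spec$nestedPairs, `[[`, character(1), "parent")
  childLab <- vapply(spec$nestedPairs, `[[`, character(1), "child")
  childFrac <- vapply(spec$nestedPairs, `[[`, numeric(1), "fraction")

  withr::with_seed(seed, {
    ancestor <- strsplit(.randomSeq(spec$markerLength), "")[[1L]]
    seqs <- character(0)
    glist <- list()
    sites <- list()
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      off <- offsets[gi]   # 0-based? offsets computed 1-based start below
      backbone <- .mutateBases(ancestor, spec$betweenRate)
      backbone <- .plantSite(backbone, off + 1L, spec$siteLength,
                             spec$siteSubstitutions)
      protect <- (off + 1L):(off + spec$siteLength)

      ci <- which(childOf == g)
      childIdx <- integer(0)
      childProtect <- integer(0)
      childBackbone <- NULL
      if (length(ci)) {
        ci <- ci[1L]
        cOff <- offsets[spec$nGroups + ci]
        childBackbone <- .plantSite(backbone, cOff + 1L, spec$siteLength,
                                    spec$siteSubstitutions)
        childProtect <- (cOff + 1L):(cOff + spec$siteLength)
        childIdx <- seq_len(max(1L, round(childFrac[ci] *
                                          spec$strainsPerGroup)))
        sites[[childLab[ci]]] <- data.frame(
          group = childLab[ci], site_start = cOff,
          site_length = spec$siteLength,
          site_seq = paste(childBackbone[childProtect], collapse = ""))
      }
      sites[[g]] <- data.frame(
        group = g, site_start = off, site_length = spec$siteLength,
        site_seq = paste(backbone[protect], collapse = ""))

      for (si in seq_len(spec$strainsPerGroup)) {
        isChild <- si %in% childIdx
        base <- if (isChild) childBackbone else backbone
        prot <- if (isChild) c(protect, childProtect) else protect
        s <- .mutateBases(base, spec$withinRate, protected = prot)
        id <- sprintf("%s_s%02d", g, si)
        seqs[[id]] <- paste(s, collapse = "")
        glist[[id]] <- if (isChild) c(g, childLab[ci]) else g
      }
    }
  })
  if (spec$primerFlanks) {
    shift <- nchar(.LEFT_FLANK)
    seqs <- paste0(.LEFT_FLANK, seqs, .RIGHT_FLANK)
    names(seqs) <- names(glist)
  } else shift <- 0L
  sites <- do.call(rbind, sites)
  sites$site_start <- sites$site_start + shift
  rownames(sites) <- NULL
  list(collection = strainCollection(seqs, glist), sites = sites)
}

#' Specification of synthetic habitat environments
#'
#' pH is drawn uniformly over its range; conductivity is linear in pH with
#' positive slope plus Gaussian noise (acidic habitats have low
#' conductivity); absorbance at 250 nm (a DOC proxy) decreases with pH;
#' oxygen and temperature are independent Gaussians; altitude decreases
#' with pH (acidic habitats lie higher).
#'
#' @param nHabitats number of habitats (>= 2)
#' @param phRange pH range, default 3.9-8.5
#' @param condSlope,condSd conductivity (uS/cm) slope per pH unit and noise
#'   SD; intercept fixed so values stay positive
#' @param a250Sd,o2Mean,o2Sd,tempMean,tempSd,altSd remaining variable
#'   parameters
#' @param seed default seed for \code{\link{generateHabitats}}
#' @return classed list
#' @export
habitatSpec <- function(nHabitats = 121L, phRange = c(3.9, 8.5),
                        condSlope = 40, condSd = 40, a250Sd = 0.08,
                        o2Mean = 8, o2Sd = 2, tempMean = 15, tempSd = 4,
                        altSd = 150, seed = 1L) {
  if (nHabitats < 2L) stop("need at least 2 habitats")
  if (diff(phRange) <= 0) stop("degenerate pH range")
  structure(list(nHabitats = as.integer(nHabitats), phRange = phRange,
                 condSlope = condSlope, condSd = condSd, a250Sd = a250Sd,
                 o2Mean = o2Mean, o2Sd = o2Sd, tempMean = tempMean,
                 tempSd = tempSd, altSd = altSd, seed = as.integer(seed)),
            class = "HabitatSpec")
}

#' Generate a synthetic environmental table
#'
#' @param spec a \code{\link{habitatSpec}}
#' @param seed integer seed
#' @return data.frame (habitats as rows) with columns pH, conductivity,
#'   A250, O2, temperature, altitude
#' @export
generateHabitats <- function(spec = habitatSpec(), seed = spec$seed) {
  withr::with_seed(seed, {
    n <- spec$nHabitats
    ph <- runif(n, spec$phRange[1L], spec$phRange[2L])
    cond <- pmax(5, -80 + spec$condSlope * ph + rnorm(n, 0, spec$condSd))
    a250 <- pmax(0.01, 1.3 - 0.13 * ph + rnorm(n, 0, spec$a250Sd))
    o2 <- pmax(0, rnorm(n, spec$o2Mean, spec$o2Sd))
    temp <- rnorm(n, spec$tempMean, spec$tempSd)
    alt <- pmax(200, 1500 - 120 * ph + rnorm(n, 0, spec$altSd))
  })
  d <- data.frame(pH = ph, conductivity = cond, A250 = a250, O2 = o2,
                  temperature = temp, altitude = alt)
  rownames(d) <- sprintf("H%03d", seq_len(spec$nHabitats))
  d
}

#' Gaussian niche specification for community assembly
#'
#' Per group: occurrence probability
#' \code{pmax * exp(-(x - mu)^2 / (2 sigma^2))} evaluated at the habitat's
#' driving variable; abundance given presence is log-normal.
#'
#' @param groups group labels
#' @param mu niche optima (units of the driving variable)
#' @param sigma niche breadths (> 0)
#' @param pmax maximal occupancy probabilities in (0, 1] (0 allowed to
#'   model a never-present group)
#' @param variable driving environmental variable (column of the habitat
#'   table)
#' @param abundanceMeanlog,abundanceSdlog log-normal abundance parameters
#' @return classed data.frame
#' @export
nicheSpec <- function(groups, mu, sigma = 0.8, pmax = 0.9,
                      variable = "pH", abundanceMeanlog = -1,
                      abundanceSdlog = 0.5) {
  d <- data.frame(group = groups, mu = mu,
                  sigma = rep_len(sigma, length(groups)),
                  pmax = rep_len(pmax, length(groups)))
  if (any(d$sigma <= 0)) stop("sigma must be > 0")
  if (any(d$pmax < 0 | d$pmax > 1)) stop("pmax must be in [0, 1]")
  structure(d, variable = variable, abundanceMeanlog = abundanceMeanlog,
            abundanceSdlog = abundanceSdlog, class = c("NicheSpec",
                                                       "data.frame"))
}

.defaultNiches <- function(groups, phRange = c(3.9, 8.5)) {
  lo <- phRange[1L] + 0.1 * diff(phRange)
  hi <- phRange[2L] - 0.1 * diff(phRange)
  nicheSpec(groups, mu = seq(lo, hi, length.out = length(groups)),
            sigma = 0.8, pmax = 0.9)
}

#' Assemble habitat communities by ecotype sorting
#'
#' Per habitat and group, presence is Bernoulli with the Gaussian-niche
#' probability; each present group contributes one uniformly chosen member
#' strain with log-normal abundance; pools are normalized per habitat.
#'
#' @param env habitat table (\code{\link{generateHabitats}})
#' @param niches a \code{\link{nicheSpec}}
#' @param collection a \linkS4class{StrainCollection} containing every
#'   niche group
#' @param seed integer seed
#' @return list with \code{pools} (data.frame habitat_id, strain_id,
#'   abundance, group) and \code{truth} (binary habitats x groups realized
#'   presence matrix)
#' @export
generatePools <- function(env, niches, collection, seed = 1L) {
  xvar <- attr(niches, "variable")
  if (!xvar %in% colnames(env)) stop("driving variable not in env: ", xvar)
  memb <- lapply(setNames(niches$group, niches$group),
                 function(g) groupMembers(collection, g))
  x <- env[[xvar]]
  habitats <- rownames(env)
  truth <- matrix(0L, nrow = length(habitats), ncol = nrow(niches),
                  dimnames = list(habitats, niches$group))
  rows <- list()
  withr::with_seed(seed, {
    for (h in seq_along(habitats)) {
      for (gi in seq_len(nrow(niches))) {
        p <- niches$pmax[gi] *
          exp(-(x[h] - niches$mu[gi])^2 / (2 * niches$sigma[gi]^2))
        if (rbinom(1L, 1L, p) == 1L) {
          truth[h, gi] <- 1L
          strain <- memb[[gi]][sample.int(length(memb[[gi]]), 1L)]
          ab <- rlnorm(1L, attr(niches, "abundanceMeanlog"),
                       attr(niches, "abundanceSdlog"))
          rows[[length(rows) + 1L]] <- data.frame(
            habitat_id = habitats[h], strain_id = strain, abundance = ab,
            group = niches$group[gi])
        }
      }
    }
  })
  pools <- if (length(rows)) do.call(rbind, rows) else
    data.frame(habitat_id = character(0), strain_id = character(0),
               abundance = numeric(0), group = character(0))
  if (nrow(pools)) {
    tot <- tapply(pools$abundance, pools$habitat_id, sum)
    pools$abundance <- pools$abundance /
      as.numeric(tot[as.character(pools$habitat_id)])
  }
  list(pools = pools, truth = truth)
}

#' Generate a complete synthetic study bundle
#'
#' Writes FASTA, group map, environmental table, pools, ground-truth
#' presence matrix and a JSON manifest recording every spec and seed; a
#' fresh run with the same arguments reproduces all files byte-identically.
#'
#' @param dir output directory (created if needed)
#' @param cSpec,hSpec \code{\link{collectionSpec}} /
#'   \code{\link{habitatSpec}}
#' @param niches a \code{\link{nicheSpec}}; NULL for evenly spaced default
#'   optima across the pH range
#' @param seed master seed; component seeds are derived as seed, seed+1,
#'   seed+2
#' @return (invisibly) list with the in-memory objects and file paths
#' @export
generateStudy <- function(dir, cSpec = collectionSpec(),
                          hSpec = habitatSpec(), niches = NULL, seed = 1L) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("output directory not writable: ", dir)
  gen <- generateCollection(cSpec, seed = seed)
  env <- generateHabitats(hSpec, seed = seed + 1L)
  if (is.null(niches))
    niches <- .defaultNiches(sprintf("G%02d", seq_len(cSpec$nGroups)),
                             hSpec$phRange)
  pg <- generatePools(env, niches, gen$collection, seed = seed + 2L)

  paths <- list(
    fasta = file.path(dir, "strains.fasta"),
    groups = file.path(dir, "groups.tsv"),
    env = file.path(dir, "env.tsv"),
    pools = file.path(dir, "pools.tsv"),
    truth = file.path(dir, "truth.tsv"),
    sites = file.path(dir, "sites.tsv"),
    manifest = file.path(dir, "manifest.json"))
  writeFasta(strainSeqs(gen$collection), paths$fasta)
  gmap <- data.frame(
    strain_id = strainIds(gen$collection),
    groups = vapply(gen$collection@groups[strainIds(gen$collection)],
                    paste, character(1), collapse = ","))
  .writeTsv(gmap, paths$groups)
  .writeTsv(env, paths$env, rownames_as = "habitat_id")
  .writeTsv(pg$pools, paths$pools)
  .writeTsv(as.data.frame(pg$truth), paths$truth, rownames_as = "habitat_id")
  .writeTsv(gen$sites, paths$sites)
  manifest <- list(seed = seed,
                   seeds = list(collection = seed, habitats = seed + 1L,
                                pools = seed + 2L),
                   collectionSpec = unclass(cSpec),
                   habitatSpec = unclass(hSpec),
                   nicheSpec = c(as.list(as.data.frame(niches)),
                                 list(variable = attr(niches, "variable"))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(collection = gen$collection, sites = gen$sites, env = env,
                 pools = pg$pools, truth = pg$truth, niches = niches,
                 paths = paths))
}

#' Benchmark fixture: a within-group SNP inside the only diagnostic window
#'
#' Builds a two-group collection in which the target group differs from
#' the background group at exactly two sites (so any probe meeting a
#' 2-mismatch specificity floor must span both) and carries a two-allele
#' SNP in between.  The top-ranked probe for the target group must then
#' contain exactly one IUPAC degenerate position covering both alleles.
#'
#' @param seed integer seed
#' @param nPerGroup strains per group (even; half per SNP allele)
#' @param coreLength backbone length
#' @return list with \code{collection}, \code{group} (the target group
#'   label) and \code{snpPosition} (0-based position of the SNP column)
#' @export
generateSnpCollection <- function(seed = 1L, nPerGroup = 6L,
                                  coreLength = 120L) {
  withr::with_seed(seed, {
    backbone <- strsplit(.randomSeq(coreLength), "")[[1L]]
    siteStart <- 51L                        # 1-based
    mutPos <- siteStart + c(8L, 11L)        # the two group-diagnostic sites
    snpPos <- siteStart + 9L                # strictly between them
    siteBases <- backbone
    for (i in mutPos)
      siteBases[i] <- sample(setdiff(.BASES, backbone[i]), 1L)
    altAllele <- sample(setdiff(.BASES, siteBases[snpPos]), 1L)
  })
  seqs <- character(0)
  glist <- list()
  for (i in seq_len(nPerGroup)) {
    s <- siteBases
    if (i > nPerGroup / 2) s[snpPos] <- altAllele
    id <- sprintf("A_s%02d", i)
    seqs[[id]] <- paste(s, collapse = "")
    glist[[id]] <- "A"
  }
  for (i in seq_len(nPerGroup)) {
    id <- sprintf("B_s%02d", i)
    seqs[[id]] <- paste(backbone, collapse = "")
    glist[[id]] <- "B"
  }
  list(collection = strainCollection(seqs, glist), group = "A",
       snpPosition = snpPos - 1L)
}
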