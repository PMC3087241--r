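# In silico PCR (single-round and nested) and RLBH signal simulation.
# The simulator is site logic: primer binding sites with a mismatch budget
# and a 3' clamp, amplicons as template slices, probe detection inside
# amplicons, and a linear signal model with ordinal class cut points.
# Thermal-cycling parameters are metadata only.

#' Construct a primer pair
#'
#' @param forward,reverse \linkS4class{DegenerateOligo} or sequence
#'   strings; both 5'->3', the reverse primer on the opposite strand (its
#'   plus-strand binding site is its reverse complement)
#' @param maxMismatches mismatch budget per site (default 1: specific
#'   primers)
#' @param clamp number of 3'-terminal primer bases in which no mismatch is
#'   tolerated (default 3)
#' @return a \linkS4class{PrimerPair}
#' @export
primerPair <- function(forward, reverse, maxMismatches = 1L, clamp = 3L) {
  new("PrimerPair", forward = .asOligo(forward, "fwd"),
      reverse = .asOligo(reverse, "rev"),
      maxMismatches = as.integer(maxMismatches), clamp = as.integer(clamp))
}

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair: %s / %s (max %d mm, 3' clamp %d)\n",
              object@forward@sequence, object@reverse@sequence,
              object@maxMismatches, object@clamp))
})

#' Find primer binding sites on a template
#'
#' Scans both strands for windows with at most \code{maxMm} mismatches and
#' no mismatch in the \code{clamp} 3'-terminal primer bases.  Plus-strand
#' sites are windows matching the primer itself; minus-strand sites are
#' windows matching its reverse complement (so the primer anneals to the
#' plus strand).  Starts are 0-based template coordinates, sorted.
#'
#' @param target concrete template sequence
#' @param primer \linkS4class{DegenerateOligo} or sequence string
#' @param maxMm mismatch budget
#' @param clamp 3' clamp length
#' @return data.frame with columns start, strand ("+"/"-"), mismatches
#' @export
findPrimerSites <- function(target, primer, maxMm = 1L, clamp = 3L) {
  o <- .encodeSeq(oligoSequence(.asOligo(primer)))
  t <- .encodeSeq(target)
  if (length(t) <= length(o)) stop("target must be longer than the primer")
  plus <- scan_sites_c(o, t, maxMm, clamp, clamp_at_start = FALSE)
  orc <- .encodeSeq(revComp(oligoSequence(.asOligo(primer))))
  minus <- scan_sites_c(orc, t, maxMm, clamp, clamp_at_start = TRUE)
  d <- rbind(
    if (nrow(plus)) data.frame(start = plus$start, strand = "+",
                               mismatches = plus$mismatches) else NULL,
    if (nrow(minus)) data.frame(start = minus$start, strand = "-",
                                mismatches = minus$mismatches) else NULL)
  if (is.null(d))
    d <- data.frame(start = integer(0), strand = character(0),
                    mismatches = integer(0))
  d[order(d$start, d$strand), , drop = FALSE]
}

.templateSeqs <- function(x) {
  if (is(x, "StrainCollection")) strainSeqs(x)
  else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("template", seq_along(x))
    x
  } else stop("templates must be a StrainCollection or named character")
}

#' In silico PCR amplification
#'
#' For each template, every pairing of a forward-primer site on the plus
#' strand with a downstream reverse-primer site on the minus strand yields
#' one amplicon spanning the forward site start to the reverse site end
#' (0-based, half-open), subject to the product length bounds.
#'
#' @param templates a \linkS4class{StrainCollection} or named character
#'   vector of concrete sequences
#' @param pair a \linkS4class{PrimerPair}
#' @param lengthBounds (min, max) product length in nt
#' @return data.frame with columns source_strain, start, end, length,
#'   sequence, round
#' @export
amplify <- function(templates, pair, lengthBounds = c(40L, 5000L)) {
  if (lengthBounds[2L] < lengthBounds[1L]) stop("inverted length bounds")
  seqs <- .templateSeqs(templates)
  out <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    fl <- nchar(pair@forward@sequence)
    rl <- nchar(pair@reverse@sequence)
    if (nchar(s) <= max(fl, rl)) return(NULL)
    sites <- list(
      f = findPrimerSites(s, pair@forward, pair@maxMismatches, pair@clamp),
      r = findPrimerSites(s, pair@reverse, pair@maxMismatches, pair@clamp))
    f <- sites$f[sites$f$strand == "+", , drop = FALSE]
    r <- sites$r[sites$r$strand == "-", , drop = FALSE]
    if (!nrow(f) || !nrow(r)) return(NULL)
    combos <- expand.grid(fi = seq_len(nrow(f)), ri = seq_len(nrow(r)))
    res <- lapply(seq_len(nrow(combos)), function(k) {
      sf <- f$start[combos$fi[k]]
      sr <- r$start[combos$ri[k]]
      if (sr < sf + fl) return(NULL)
      end <- sr + rl
      len <- end - sf
      if (len < lengthBounds[1L] || len > lengthBounds[2L]) return(NULL)
      data.frame(source_strain = id, start = sf, end = end, length = len,
                 sequence = substr(s, sf + 1L, end), round = "single")
    })
    do.call(rbind, res)
  })
  d <- do.call(rbind, out)
  if (is.null(d))
    d <- data.frame(source_strain = character(0), start = integer(0),
                    end = integer(0), length = integer(0),
                    sequence = character(0), round = character(0))
  stopifnot(all(d$end > d$start | !nrow(d)))
  rownames(d) <- NULL
  d
}

#' Nested in silico PCR
#'
#' Amplifies with the outer pair, then re-amplifies each outer product with
#' the inner pair; inner products are marked \code{round = "nested"} and
#' keep source-template coordinates.
#'
#' @param templates as in \code{\link{amplify}}
#' @param outer,inner \linkS4class{PrimerPair}s
#' @param outerBounds,innerBounds product length bounds per round
#' @return data.frame as \code{\link{amplify}}
#' @export
nestedAmplify <- function(templates, outer, inner,
                          outerBounds = c(40L, 5000L),
                          innerBounds = c(40L, 5000L)) {
  first <- amplify(templates, outer, outerBounds)
  if (!nrow(first))
    return(first)
  prods <- setNames(first$sequence,
                    paste0(first$source_strain, "|", first$start))
  second <- amplify(prods, inner, innerBounds)
  if (!nrow(second)) {
    second$round <- character(0)
    return(second)
  }
  meta <- strsplit(second$source_strain, "|", fixed = TRUE)
  outerStart <- vapply(meta, function(m) as.integer(m[2L]), integer(1))
  second$source_strain <- vapply(meta, `[`, character(1), 1L)
  second$start <- second$start + outerStart
  second$end <- second$end + outerStart
  second$round <- "nested"
  rownames(second) <- NULL
  second
}

#' RLBH hybridization signal model
#'
#' Signal is linear in the summed relative abundance of pool members whose
#' amplicon carries a probe site within the mismatch tolerance, scaled by a
#' per-probe gain (the in silico analogue of probe-concentration
#' compensation).  Two cut points split positive signals into ordinal
#' classes.
#'
#' @param gains per-probe positive multipliers; a single value is recycled
#' @param detectionFloor minimum signal called at all (default 1e-3)
#' @param thresholds two increasing cut points separating weak / average /
#'   very_strong (defaults 1e-2 and 1e-1 of the maximal attainable signal
#'   at gain 1)
#' @param mismatchTolerance probe-site mismatches still counted as bound
#'   (default 0: perfect match)
#' @return classed list
#' @export
hybridizationModel <- function(gains = 1, detectionFloor = 1e-3,
                               thresholds = c(1e-2, 1e-1),
                               mismatchTolerance = 0L) {
  if (any(gains <= 0)) stop("gains must be > 0")
  if (length(thresholds) != 2L || diff(thresholds) <= 0)
    stop("thresholds must be two strictly increasing cut points")
  structure(list(gains = gains, detectionFloor = detectionFloor,
                 thresholds = thresholds,
                 mismatchTolerance = as.integer(mismatchTolerance)),
            class = "HybridizationModel")
}

.classify <- function(signal, model) {
  ifelse(signal < model$detectionFloor, "none",
  ifelse(signal < model$thresholds[1L], "weak",
  ifelse(signal < model$thresholds[2L], "average", "very_strong")))
}

# Amplicons of one template under either a single pair or a nested scheme.
.amplifyScheme <- function(seqs, primers, lengthBounds) {
  if (is(primers, "PrimerPair")) {
    amplify(seqs, primers, lengthBounds)
  } else if (is.list(primers) && all(c("outer", "inner") %in% names(primers))) {
    nestedAmplify(seqs, primers$outer, primers$inner,
                  outerBounds = lengthBounds, innerBounds = lengthBounds)
  } else stop("primers must be a PrimerPair or list(outer =, inner =)")
}

#' Simulate one RLBH row (a habitat pool against a probe panel)
#'
#' Members of the pool are amplified (single or nested PCR); a probe scores
#' a member when some amplicon contains a probe site within the mismatch
#' tolerance (either strand); the probe signal is the gain-weighted summed
#' abundance of scoring members, classified into ordinal classes.
#'
#' @param panel a \linkS4class{ProbePanel}
#' @param pool data.frame with columns strain_id, abundance (one habitat);
#'   abundances are normalized
#' @param collection the \linkS4class{StrainCollection} the pool draws from
#' @param model a \code{\link{hybridizationModel}}
#' @param primers a \linkS4class{PrimerPair} or \code{list(outer =, inner =)}
#' @param lengthBounds PCR product length bounds
#' @return list with \code{signal} and \code{class}, named by probe
#' @export
hybridize <- function(panel, pool, collection, model = hybridizationModel(),
                      primers, lengthBounds = c(40L, 5000L)) {
  probes <- panel@probes
  gains <- rep_len(model$gains, nrow(probes))
  if (!is.null(names(model$gains))) {
    gains <- rep_len(1, nrow(probes))
    known <- intersect(names(model$gains), probes$probe)
    gains[match(known, probes$probe)] <- model$gains[known]
  }
  signal <- setNames(numeric(nrow(probes)), probes$probe)
  if (nrow(pool)) {
    ab <- pool$abundance / sum(pool$abundance)
    seqs <- strainSeqs(collection)[pool$strain_id]
    amp <- .amplifyScheme(seqs, primers, lengthBounds)
    stopifnot(all(amp$sequence ==
                  substr(strainSeqs(collection)[amp$source_strain],
                         amp$start + 1L, amp$end)) || !nrow(amp))
    for (i in seq_len(nrow(probes))) {
      plen <- nchar(probes$sequence[i])
      hitStrain <- unique(amp$source_strain[vapply(seq_len(nrow(amp)),
        function(k) nchar(amp$sequence[k]) >= plen &&
          minMismatches(probes$sequence[i], amp$sequence[k],
                        strands = "both")$mismatches <=
          model$mismatchTolerance, logical(1))])
      bound <- pool$strain_id %in% hitStrain
      signal[i] <- gains[i] * sum(ab[bound])
    }
  }
  list(signal = signal, class = setNames(.classify(signal, model),
                                         probes$probe))
}

#' Simulate a full detection matrix over many habitat pools
#'
#' @param panel,collection,model,primers,lengthBounds as in
#'   \code{\link{hybridize}}
#' @param pools data.frame with columns habitat_id, strain_id, abundance
#' @param habitats habitat ids for the matrix rows; defaults to the
#'   habitats present in \code{pools}, but passing the full habitat list
#'   keeps empty communities as all-\code{none} rows
#' @return a \linkS4class{DetectionMatrix} (habitats x probes)
#' @export
hybridizePools <- function(panel, pools, collection,
                           model = hybridizationModel(), primers,
                           lengthBounds = c(40L, 5000L),
                           habitats = unique(as.character(pools$habitat_id))) {
  probes <- panel@probes$probe
  sig <- matrix(0, nrow = length(habitats), ncol = length(probes),
                dimnames = list(habitats, probes))
  cls <- matrix("none", nrow = length(habitats), ncol = length(probes),
                dimnames = list(habitats, probes))
  for (h in habitats) {
    row <- hybridize(panel, pools[pools$habitat_id == h, , drop = FALSE],
                     collection, model, primers, lengthBounds)
    sig[h, ] <- row$signal
    cls[h, ] <- row$class
  }
  new("DetectionMatrix", signal = sig, classes = cls,
      metadata = list(model = model,
                      scheme = if (is(primers, "PrimerPair")) "single"
                               else "nested"))
}

#' @describeIn hybridizePools raw signal matrix accessor
#' @param x a \linkS4class{DetectionMatrix}
#' @export
signalMatrix <- function(x) x@signal

#' @describeIn hybridizePools ordinal class matrix accessor
#' @export
classMatrix <- function(x) x@classes

setMethod("show", "DetectionMatrix", function(object) {
  cat(sprintf("DetectionMatrix: %d habitats x %d probes\n",
              nrow(object@signal), ncol(object@signal)))
  tab <- table(factor(object@classes, levels = .SIGNAL_CLASSES))
  cat("  classes: ", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n", sep = "")
})

#' Binarize a detection matrix
#'
#' Default rule counts any signal class above \code{none} as present;
#' \code{exclude_weak} additionally zeroes weak signals (sensitivity
#' analysis).  Idempotent on an already-binary 0/1 matrix.
#'
#' @param x a \linkS4class{DetectionMatrix} or a 0/1 matrix
#' @param rule binarization rule
#' @return integer 0/1 matrix, habitats x probes
#' @export
binarize <- function(x, rule = c("any_signal", "exclude_weak")) {
  rule <- match.arg(rule)
  if (is.matrix(x) && all(x %in% c(0L, 1L))) {
    storage.mode(x) <- "integer"
    return(x)
  }
  if (!is(x, "DetectionMatrix"))
    stop("x must be a DetectionMatrix or a 0/1 matrix")
  keep <- if (rule == "any_signal") c("weak", "average", "very_strong")
          else c("average", "very_strong")
  out <- matrix(as.integer(x@classes %in% keep), nrow = nrow(x@classes),
                dimnames = dimnames(x@classes))
  out
}
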