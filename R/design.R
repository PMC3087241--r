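# Group-specific probe design: window enumeration on a within-group column
# profile, IUPAC degenerate-code emission at within-group variant columns,
# constraint filtering (Tm window, coverage, non-target mismatch floor) and
# deterministic ranked-greedy panel selection.

#' Probe design constraints
#'
#' @param lengthRange allowed probe lengths in nt (min >= 8)
#' @param tmWindow optional absolute Tm window (low, high) in degrees C;
#'   NULL disables the absolute window (the panel spread is still bounded
#'   via \code{tmTolerance})
#' @param tmTolerance half-width of the tolerated panel Tm spread: a
#'   designed panel keeps \code{max(Tm) - min(Tm) <= 2 * tmTolerance}
#' @param minGroupCoverage fraction of target-group strains that must be
#'   perfect-matched, in (0, 1]
#' @param minNontargetMismatches minimum mismatches to every non-target
#'   strain (hard floor 1)
#' @param maxDegeneratePositions maximum IUPAC ambiguity codes per probe
#' @param centralWeighting prefer candidates whose non-target mismatches
#'   fall in the central third of the probe (terminal mismatches
#'   discriminate poorly in hybridization)
#' @return classed list of constraints
#' @export
designConstraints <- function(lengthRange = c(18L, 31L), tmWindow = NULL,
                              tmTolerance = 10, minGroupCoverage = 1.0,
                              minNontargetMismatches = 2L,
                              maxDegeneratePositions = 2L,
                              centralWeighting = TRUE) {
  if (lengthRange[1L] < 8L) stop("minimum probe length must be >= 8")
  if (lengthRange[2L] < lengthRange[1L]) stop("invalid lengthRange")
  if (minGroupCoverage <= 0 || minGroupCoverage > 1)
    stop("minGroupCoverage must be in (0, 1]")
  if (minNontargetMismatches < 1L)
    stop("minNontargetMismatches has a hard floor of 1")
  if (!is.null(tmWindow) && tmWindow[2L] < tmWindow[1L])
    stop("invalid tmWindow")
  structure(list(lengthRange = as.integer(lengthRange), tmWindow = tmWindow,
                 tmTolerance = tmTolerance,
                 minGroupCoverage = minGroupCoverage,
                 minNontargetMismatches = as.integer(minNontargetMismatches),
                 maxDegeneratePositions = as.integer(maxDegeneratePositions),
                 centralWeighting = isTRUE(centralWeighting)),
            class = "DesignConstraints")
}

# Column profile of a group: every member is placed on the coordinates of
# the first member by its best-scoring gapless offset, and each column
# collects the union (bitwise OR) of the member bases.  Columns not covered
# by all members are marked invalid.
.groupProfile <- function(enc, memberIdx) {
  ref <- enc$fwd[[memberIdx[1L]]]
  P <- length(ref)
  profile <- ref
  covered <- matrix(FALSE, nrow = length(memberIdx), ncol = P)
  covered[1L, ] <- TRUE
  if (length(memberIdx) > 1L) {
    for (k in 2L:length(memberIdx)) {
      q <- enc$fwd[[memberIdx[k]]]
      off <- best_offset_c(q, ref, min_overlap = min(length(q), P, 30L))$offset
      # query position i (1-based) aligns to ref position i + off
      i <- seq_along(q)
      p <- i + off
      keep <- p >= 1L & p <= P
      profile[p[keep]] <- bitwOr(profile[p[keep]], q[i[keep]])
      covered[k, p[keep]] <- TRUE
    }
  }
  list(mask = profile, valid = colSums(covered) == length(memberIdx),
       refLength = P)
}

# All (start, length) windows on the profile that satisfy the degeneracy
# constraints; starts are 0-based.
.profileWindows <- function(profile, lengthRange, maxDeg) {
  isDeg <- .maskWidth(profile$mask) > 1L
  degCum <- c(0L, cumsum(isDeg))
  invCum <- c(0L, cumsum(!profile$valid))
  out <- vector("list", diff(lengthRange) + 1L)
  for (li in seq_along(out)) {
    l <- lengthRange[1L] + li - 1L
    if (l > profile$refLength) break
    s <- 0:(profile$refLength - l)
    nDeg <- degCum[s + l + 1L] - degCum[s + 1L]
    nInv <- invCum[s + l + 1L] - invCum[s + 1L]
    keep <- nInv == 0L & nDeg <= maxDeg
    if (any(keep))
      out[[li]] <- data.frame(start = s[keep], length = l,
                              n_degenerate = nDeg[keep])
  }
  do.call(rbind, out)
}

.decodeWindow <- function(mask, start, len) {
  .decodeMask(mask[(start + 1L):(start + len)])
}

# Mismatches in the central third of the probe against the best window of
# one target (encoded fwd/rc masks; used by the central-weighting
# tie-break).
.centralMismatches <- function(candMask, tFwd, tRc) {
  L <- length(candMask)
  best <- NULL
  for (t in list(tFwd, tRc)) {
    hit <- scan_min_c(candMask, t)
    if (is.null(best) || hit$mismatches < best$mm)
      best <- list(mm = hit$mismatches, t = t, s = hit$start)
  }
  win <- best$t[(best$s + 1L):(best$s + L)]
  mmPos <- which(bitwAnd(candMask, win) == 0L)
  third <- ceiling(L / 3)
  sum(mmPos > third & mmPos <= L - third)
}

#' Enumerate group-specific probe candidates
#'
#' Every window of each allowed length is considered on a within-group
#' column profile (members aligned to the first member by best gapless
#' offset); within-group variant columns become IUPAC degenerate codes, up
#' to the constraint limit.  Candidates failing the Tm window, the group
#' coverage, or the non-target mismatch floor are dropped; the survivors
#' are deduplicated and sorted by (coverage desc, non-target minimum
#' mismatches desc, [central mismatches desc when central weighting is on,]
#' degeneracy asc, Tm distance to the window centre asc, source position
#' asc).  An empty result is a valid outcome (a group without any
#' discriminative window).
#'
#' @param collection a \linkS4class{StrainCollection}
#' @param group target group label
#' @param constraints a \code{\link{designConstraints}}
#' @param model a \code{\link{tmModel}} for candidate Tm values
#' @param enc pre-encoded collection (internal reuse)
#' @return data.frame of candidates (possibly 0 rows) with columns
#'   sequence, group, source_strain, start (0-based), length, coverage,
#'   nontarget_min_mm, nearest_nontarget, central_mm, degeneracy,
#'   n_degenerate, tm
#' @export
enumerateCandidates <- function(collection, group,
                                constraints = designConstraints(),
                                model = tmModel(),
                                enc = NULL) {
  members <- groupMembers(collection, group)   # errors on unknown group
  if (is.null(enc)) enc <- .encodeCollection(collection)
  ids <- enc$ids
  memberIdx <- match(members, ids)
  nontarget <- match(.nontargetIds(collection, group), ids)

  profile <- .groupProfile(enc, memberIdx)
  win <- .profileWindows(profile, constraints$lengthRange,
                         constraints$maxDegeneratePositions)
  empty <- data.frame(sequence = character(0), group = character(0),
                      source_strain = character(0), start = integer(0),
                      length = integer(0), coverage = numeric(0),
                      nontarget_min_mm = integer(0),
                      nearest_nontarget = character(0),
                      central_mm = integer(0), degeneracy = integer(0),
                      n_degenerate = integer(0), tm = numeric(0))
  if (is.null(win) || !nrow(win)) return(empty)

  # absolute Tm window (pre-filter when requested; mask-based batch)
  if (!is.null(constraints$tmWindow)) {
    win$tm <- .tmBatchWindows(profile$mask, win$start, win$length, model)
    win <- win[win$tm >= constraints$tmWindow[1L] &
               win$tm <= constraints$tmWindow[2L], , drop = FALSE]
    if (!nrow(win)) return(empty)
  }

  # specificity floor: single pass with per-window early exit and
  # candidate-level abort; complete (exact) for surviving candidates
  if (length(nontarget)) {
    sp <- specificity_scan_c(win$start, win$length, profile$mask,
                             enc$fwd, enc$rc, nontarget,
                             constraints$minNontargetMismatches)
    win$nontarget_min_mm <- sp$min_mm
    win$nearest_nontarget <- ids[sp$nearest]
    win <- win[sp$pass, , drop = FALSE]
    if (!nrow(win)) return(empty)
  } else {
    win$nontarget_min_mm <- win$length + 1L   # no non-target strains
    win$nearest_nontarget <- NA_character_
  }

  decoded <- .decodeMask(profile$mask)
  win$sequence <- substring(decoded, win$start + 1L, win$start + win$length)
  win <- win[!duplicated(win$sequence), , drop = FALSE]

  win$coverage <- batch_coverage_c(win$start, win$length, profile$mask,
                                   enc$fwd, enc$rc, memberIdx)
  win <- win[win$coverage >= constraints$minGroupCoverage, , drop = FALSE]
  if (!nrow(win)) return(empty)

  if (is.null(win$tm))
    win$tm <- .tmBatchWindows(profile$mask, win$start, win$length, model)
  cumLog <- c(0, cumsum(log2(.maskWidth(profile$mask))))
  win$degeneracy <- as.integer(round(
    2^(cumLog[win$start + win$length + 1L] - cumLog[win$start + 1L])))
  win$central_mm <- if (constraints$centralWeighting) {
    vapply(seq_len(nrow(win)), function(i) {
      if (is.na(win$nearest_nontarget[i])) return(0L)
      ni <- match(win$nearest_nontarget[i], ids)
      .centralMismatches(
        profile$mask[(win$start[i] + 1L):(win$start[i] + win$length[i])],
        enc$fwd[[ni]], enc$rc[[ni]])
    }, integer(1))
  } else rep(0L, nrow(win))

  tmDist <- if (is.null(constraints$tmWindow)) rep(0, nrow(win))
            else abs(win$tm - mean(constraints$tmWindow))
  # specificity ranking key: with central weighting on, mismatches in the
  # central third count double (terminal mismatches discriminate poorly in
  # hybridization); raw minimum mismatches break remaining ties
  specKey <- win$nontarget_min_mm +
    if (constraints$centralWeighting) win$central_mm else 0L
  ord <- order(-win$coverage, -specKey, -win$nontarget_min_mm,
               win$degeneracy, tmDist, win$start)
  win <- win[ord, , drop = FALSE]
  data.frame(sequence = win$sequence, group = group,
             source_strain = ids[memberIdx[1L]], start = win$start,
             length = win$length, coverage = win$coverage,
             nontarget_min_mm = win$nontarget_min_mm,
             nearest_nontarget = win$nearest_nontarget,
             central_mm = win$central_mm, degeneracy = win$degeneracy,
             n_degenerate = win$n_degenerate, tm = win$tm,
             row.names = NULL)
}

#' Per-strain specificity of one probe candidate
#'
#' Minimum mismatches of the candidate over the full sequence of every
#' strain, both strands.  When a target group is given, the non-target
#' minimum excludes strains of the group and of any nested (super- or
#' sub-) group.
#'
#' @param candidate \linkS4class{DegenerateOligo} or sequence string
#' @param collection a \linkS4class{StrainCollection}
#' @param group optional target group label
#' @return list with \code{per_strain} (named integer vector),
#'   \code{nontarget_min_mm} and \code{nearest_nontarget} (NA without a
#'   group)
#' @export
scoreSpecificity <- function(candidate, collection, group = NULL) {
  enc <- .encodeCollection(collection)
  o <- .encodeSeq(oligoSequence(.asOligo(candidate)))
  mm <- setNames(scan_min_all_c(o, enc$fwd, enc$rc), enc$ids)
  out <- list(per_strain = mm, nontarget_min_mm = NA_integer_,
              nearest_nontarget = NA_character_)
  if (!is.null(group)) {
    nt <- .nontargetIds(collection, group)
    if (length(nt)) {
      out$nontarget_min_mm <- min(mm[nt])
      out$nearest_nontarget <- nt[which.min(mm[nt])]
    }
  }
  out
}

#' Design a group-specific probe panel
#'
#' For each group the best candidate under the \code{enumerateCandidates}
#' ordering is taken; the panel-level Tm spread is kept within
#' \code{2 * tmTolerance} by greedily substituting next-ranked candidates
#' (in group order).  Groups with no feasible candidate are reported in the
#' result, never silently dropped.
#'
#' @param collection a \linkS4class{StrainCollection}
#' @param groups group labels to design probes for (default: all groups)
#' @param constraints a \code{\link{designConstraints}}
#' @param model a \code{\link{tmModel}}
#' @return a \linkS4class{ProbePanel}; \code{strainCoverage} counts strains
#'   of the whole collection perfect-matched by at least one panel probe
#' @export
designPanel <- function(collection, groups = groupNames(collection),
                        constraints = designConstraints(),
                        model = tmModel()) {
  if (!length(groups)) stop("groups must be non-empty")
  enc <- .encodeCollection(collection)
  cands <- lapply(groups, function(g)
    enumerateCandidates(collection, g, constraints, model, enc = enc))
  names(cands) <- groups

  # Tm anchoring: centre the panel on the median Tm of the per-group top
  # candidates, then greedily (in group order) take each group's
  # best-ranked candidate inside [centre - tol, centre + tol]; groups with
  # no candidate in the band fall back to their top candidate and are
  # flagged, so the spread guarantee holds whenever the flag list is empty.
  feasible <- groups[vapply(cands, nrow, integer(1)) > 0L]
  centre <- if (length(feasible))
    stats::median(vapply(cands[feasible], function(cc) cc$tm[1L], numeric(1)))
  else NA_real_
  chosen <- list()
  tmViolated <- character(0)
  for (g in feasible) {
    cc <- cands[[g]]
    fits <- abs(cc$tm - centre) <= constraints$tmTolerance
    pick <- if (any(fits)) which(fits)[1L] else 1L
    if (!any(fits)) tmViolated <- c(tmViolated, g)
    row <- cc[pick, , drop = FALSE]
    row$probe <- g
    chosen[[g]] <- row
  }
  infeasible <- groups[vapply(cands, nrow, integer(1)) == 0L]
  probes <- if (length(chosen)) {
    d <- do.call(rbind, chosen)
    rownames(d) <- NULL
    d[, c("probe", "group", "sequence", "tm", "coverage",
          "nontarget_min_mm", "nearest_nontarget", "degeneracy",
          "n_degenerate", "central_mm", "source_strain", "start", "length")]
  } else {
    data.frame(probe = character(0), group = character(0),
               sequence = character(0), tm = numeric(0),
               coverage = numeric(0), nontarget_min_mm = integer(0),
               nearest_nontarget = character(0), degeneracy = integer(0),
               n_degenerate = integer(0), central_mm = integer(0),
               source_strain = character(0), start = integer(0),
               length = integer(0))
  }

  # whole-collection coverage: perfect match to >= 1 panel probe
  hit <- rep(FALSE, length(enc$ids))
  for (s in probes$sequence) {
    mm <- scan_min_all_c(.encodeSeq(s), enc$fwd, enc$rc)
    hit <- hit | (mm == 0L)
  }
  spread <- if (nrow(probes)) diff(range(probes$tm)) else 0
  new("ProbePanel", probes = probes,
      strainCoverage = if (length(enc$ids)) mean(hit) else NA_real_,
      uncoveredStrains = enc$ids[!hit],
      infeasibleGroups = infeasible,
      metadata = list(constraints = constraints, tmModel = model,
                      tmSpread = spread, tmSpreadViolated = tmViolated))
}

setMethod("show", "ProbePanel", function(object) {
  cat(sprintf("ProbePanel: %d probes, strain coverage %.1f%%\n",
              nrow(object@probes), 100 * object@strainCoverage))
  if (nrow(object@probes)) {
    cat(sprintf("  Tm %.1f-%.1f C\n", min(object@probes$tm),
                max(object@probes$tm)))
    print(object@probes[, c("probe", "group", "sequence", "tm", "coverage",
                            "nontarget_min_mm", "degeneracy")],
          row.names = FALSE)
  }
  if (length(object@infeasibleGroups))
    cat("  infeasible groups: ",
        paste(object@infeasibleGroups, collapse = ", "), "\n", sep = "")
})

#' Validate a probe panel against a strain collection
#'
#' A strain is called positive for a probe when its minimum mismatch count
#' (both strands, whole sequence) is zero (\code{perfectMatchOnly}) or at
#' most \code{maxMismatches}.  Calls are classified against the group
#' labels; strains of a nested child group carry the parent label too, so a
#' parent probe detecting a child strain is a true positive.
#'
#' @param panel a \linkS4class{ProbePanel}
#' @param collection a \linkS4class{StrainCollection}
#' @param perfectMatchOnly require 0 mismatches for a positive call
#' @param maxMismatches positive-call threshold when
#'   \code{perfectMatchOnly = FALSE}
#' @return a \linkS4class{ValidationReport}
#' @export
validatePanel <- function(panel, collection, perfectMatchOnly = TRUE,
                          maxMismatches = 1L) {
  thr <- if (perfectMatchOnly) 0L else as.integer(maxMismatches)
  enc <- .encodeCollection(collection)
  groups <- collection@groups
  calls <- lapply(seq_len(nrow(panel@probes)), function(i) {
    p <- panel@probes[i, ]
    mm <- scan_min_all_c(.encodeSeq(p$sequence), enc$fwd, enc$rc)
    positive <- mm <= thr
    inGroup <- vapply(enc$ids, function(s) p$group %in% groups[[s]],
                      logical(1))
    cls <- ifelse(positive & inGroup, "true_positive",
           ifelse(positive & !inGroup, "false_positive",
           ifelse(!positive & inGroup, "false_negative", "true_negative")))
    data.frame(probe = p$probe, strain = enc$ids,
               groups = vapply(groups[enc$ids], paste, character(1),
                               collapse = ","),
               mismatches = mm, classification = cls, row.names = NULL)
  })
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(probe = character(0), strain = character(0),
               groups = character(0), mismatches = integer(0),
               classification = character(0))
  summ <- if (nrow(calls)) {
    do.call(rbind, lapply(split(calls, calls$probe), function(d) {
      tp <- sum(d$classification == "true_positive")
      fp <- sum(d$classification == "false_positive")
      fn <- sum(d$classification == "false_negative")
      tn <- sum(d$classification == "true_negative")
      data.frame(probe = d$probe[1L], tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
                 row.names = NULL)
    }))
  } else {
    data.frame(probe = character(0), tp = integer(0), fp = integer(0),
               fn = integer(0), tn = integer(0), sensitivity = numeric(0),
               specificity = numeric(0))
  }
  rownames(summ) <- NULL
  new("ValidationReport", calls = calls, summary = summ)
}

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d probes x %d strains\n",
              nrow(object@summary),
              if (nrow(object@summary)) nrow(object@calls) / nrow(object@summary) else 0L))
  if (nrow(object@summary)) print(object@summary, row.names = FALSE)
})
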