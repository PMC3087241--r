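#' @importClassesFrom Biostrings DNAStringSet
NULL

#' DegenerateOligo: an IUPAC-alphabet oligonucleotide
#'
#' A probe or primer written 5'->3' over the IUPAC nucleotide alphabet
#' (A,C,G,T plus ambiguity codes R,Y,S,W,K,M,B,D,H,V,N).  The biotinylation
#' flag is carried as metadata only (labelled primers in RLBH assays).
#'
#' @slot name short label, e.g. \code{"F11"} or \code{"PnecCf-4"}
#' @slot sequence character, 5'->3', IUPAC alphabet, upper case
#' @slot biotinylated logical flag (metadata only)
#' @exportClass DegenerateOligo
setClass("DegenerateOligo",
  representation(name = "character", sequence = "character",
                 biotinylated = "logical"))

setValidity("DegenerateOligo", function(object) {
  if (length(object@sequence) != 1L || nchar(object@sequence) < 1L)
    return("sequence must be a single string of length >= 1")
  chars <- strsplit(object@sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(.IUPAC_MASK))
  if (length(bad))
    return(sprintf("invalid IUPAC character '%s' at position %d",
                   chars[bad[1L]], bad[1L]))
  if (length(object@biotinylated) != 1L) return("biotinylated must be scalar")
  TRUE
})

#' StrainCollection: labelled marker sequences
#'
#' Concrete (non-degenerate) marker sequences of a strain collection,
#' together with the (possibly nested) group membership of every strain.
#' Groups may overlap: a strain in a child group carries both the child and
#' the parent label (e.g. F15-1 strains also belong to F15).
#'
#' @slot sequences \link[Biostrings]{DNAStringSet}, one entry per strain,
#'   names are the unique strain ids
#' @slot groups named list: strain id -> character vector of group labels
#'   (may be empty: strains not targeted by probes)
#' @slot habitat named character: optional origin habitat per strain (NA
#'   when unknown)
#' @exportClass StrainCollection
setClass("StrainCollection",
  representation(sequences = "DNAStringSet", groups = "list",
                 habitat = "character"))

setValidity("StrainCollection", function(object) {
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    return("strain ids must be present and unique")
  if (!identical(sort(names(object@groups)), sort(ids)))
    return("groups list must be named by exactly the strain ids")
  seqs <- as.character(object@sequences)
  if (any(nchar(seqs) == 0L)) return("empty strain sequence")
  if (!all(grepl("^[ACGT]+$", seqs)))
    return("strain sequences must be concrete (A/C/G/T only)")
  TRUE
})

#' PrimerPair: a forward/reverse primer pair for in silico PCR
#'
#' Both primers are given 5'->3'; the reverse primer is written on the
#' opposite strand, as conventional, so its binding site on the template
#' plus strand is its reverse complement.
#'
#' @slot forward,reverse \linkS4class{DegenerateOligo}
#' @slot maxMismatches maximum mismatches tolerated per binding site
#' @slot clamp number of 3'-terminal bases in which no mismatch is allowed
#' @exportClass PrimerPair
setClass("PrimerPair",
  representation(forward = "DegenerateOligo", reverse = "DegenerateOligo",
                 maxMismatches = "integer", clamp = "integer"))

setValidity("PrimerPair", function(object) {
  if (object@maxMismatches < 0L) return("maxMismatches must be >= 0")
  if (object@clamp < 0L) return("clamp must be >= 0")
  lmin <- min(nchar(object@forward@sequence), nchar(object@reverse@sequence))
  if (object@clamp > lmin) return("clamp longer than a primer")
  TRUE
})

#' ProbePanel: an ordered set of group-specific probes
#'
#' Result of \code{\link{designPanel}} (or loaded from a panel table).  The
#' \code{probes} data frame has one row per probe with columns
#' \code{probe}, \code{group}, \code{sequence}, \code{tm}, \code{coverage},
#' \code{nontarget_min_mm}, \code{nearest_nontarget}, \code{degeneracy},
#' \code{source_strain}, \code{start}.
#'
#' @slot probes data.frame as described above
#' @slot strainCoverage fraction of all collection strains perfect-matched
#'   by at least one panel probe
#' @slot uncoveredStrains ids of strains matched by no probe
#' @slot infeasibleGroups groups for which no candidate satisfied the
#'   constraints (reported, never silently dropped)
#' @slot metadata list (design constraints, Tm model, Tm spread, notes)
#' @exportClass ProbePanel
setClass("ProbePanel",
  representation(probes = "data.frame", strainCoverage = "numeric",
                 uncoveredStrains = "character",
                 infeasibleGroups = "character", metadata = "list"))

setValidity("ProbePanel", function(object) {
  if (nrow(object@probes) && anyDuplicated(object@probes$probe))
    return("probe names must be unique")
  TRUE
})

#' ValidationReport: in silico specificity screen of a panel
#'
#' @slot calls data.frame with one row per (probe, strain):
#'   \code{probe}, \code{strain}, \code{groups}, \code{mismatches},
#'   \code{classification} in \{true_positive, false_positive,
#'   false_negative, true_negative\}
#' @slot summary data.frame with per-probe sensitivity and specificity
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(calls = "data.frame", summary = "data.frame"))

#' DetectionMatrix: habitats x probes RLBH signals
#'
#' Ordinal signal classes (\code{none}, \code{weak}, \code{average},
#' \code{very_strong}) with the underlying raw signal values, mirroring the
#' grey-scale scoring of membrane line blots.
#'
#' @slot signal numeric matrix habitats x probes (raw simulated signal)
#' @slot classes character matrix of the same shape with the ordinal class
#' @slot metadata list (hybridization model, primer scheme, notes)
#' @exportClass DetectionMatrix
setClass("DetectionMatrix",
  representation(signal = "matrix", classes = "matrix", metadata = "list"))

.SIGNAL_CLASSES <- c("none", "weak", "average", "very_strong")

setValidity("DetectionMatrix", function(object) {
  if (!identical(dim(object@signal), dim(object@classes)))
    return("signal and classes dimensions differ")
  if (!all(object@classes %in% .SIGNAL_CLASSES))
    return("unknown signal class")
  TRUE
})

#' OrdinationResult: (constrained) ordination of a detection matrix
#'
#' @slot method one of CA, CCA, PCA, RDA
#' @slot eigenvalues non-negative, descending
#' @slot totalInertia total inertia (CA/CCA) or total variance (PCA/RDA)
#' @slot constrainedFraction constrained share of total inertia in [0,1]
#'   (NA for unconstrained methods)
#' @slot siteScores,speciesScores,biplotScores score matrices (biplot scores
#'   of environmental variables; empty for unconstrained methods)
#' @slot scaling scaling convention id
#' @slot metadata list (direction, dropped rows/columns, ...)
#' @exportClass OrdinationResult
setClass("OrdinationResult",
  representation(method = "character", eigenvalues = "numeric",
                 totalInertia = "numeric", constrainedFraction = "numeric",
                 siteScores = "matrix", speciesScores = "matrix",
                 biplotScores = "matrix", scaling = "character",
                 metadata = "list"))

setValidity("OrdinationResult", function(object) {
  ev <- object@eigenvalues
  if (length(ev) && any(ev < -1e-10)) return("negative eigenvalue")
  if (length(ev) > 1L && any(diff(ev) > 1e-8))
    return("eigenvalues must be sorted descending")
  cf <- object@constrainedFraction
  if (!is.na(cf) && (cf < -1e-10 || cf > 1 + 1e-10))
    return("constrained fraction outside [0,1]")
  TRUE
})

#' ForwardSelectionResult: permutation forward selection of variables
#'
#' @slot selected data.frame (variable, added_variance, p_value,
#'   adjusted_p, n_perm) in selection order
#' @slot unselected data.frame with the p-values of the remaining variables
#'   at their last entry test
#' @slot alpha entry threshold
#' @slot method ordination method used (cca or rda)
#' @slot adjust p-value adjustment applied per entry step
#' @slot seed seed the permutation streams were derived from
#' @exportClass ForwardSelectionResult
setClass("ForwardSelectionResult",
  representation(selected = "data.frame", unselected = "data.frame",
                 alpha = "numeric", method = "character",
                 adjust = "character", seed = "numeric"))

#' CooccurrenceReport: sympatry-allopatry summary of detections
#'
#' @slot frequencies per-group detection frequency (% of habitats), for all
#'   groups of the matrix
#' @slot vennCells data.frame: one row per presence/absence combination of
#'   the chosen subset (pattern, count, percent)
#' @slot pairwiseCounts symmetric matrix of co-occurrence counts (subset)
#' @slot neverCooccur symmetric logical matrix: pair never co-occurs
#' @slot richnessMean,richnessSD mean and SD of per-habitat group richness
#' @slot nHabitats number of habitats
#' @slot subset the group labels the Venn cells refer to
#' @exportClass CooccurrenceReport
setClass("CooccurrenceReport",
  representation(frequencies = "numeric", vennCells = "data.frame",
                 pairwiseCounts = "matrix", neverCooccur = "matrix",
                 richnessMean = "numeric", richnessSD = "numeric",
                 nHabitats = "integer", subset = "character"))

setValidity("CooccurrenceReport", function(object) {
  if (nrow(object@vennCells) &&
      sum(object@vennCells$count) != object@nHabitats)
    return("Venn cell counts must sum to the habitat count")
  f <- object@frequencies
  if (length(f) && (any(f < 0) || any(f > 100)))
    return("frequencies must be percentages in [0,100]")
  TRUE
})
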