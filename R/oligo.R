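#' Construct a degenerate oligonucleotide
#'
#' @param name short label (probe or primer name)
#' @param sequence 5'->3' sequence over the IUPAC alphabet; lower case and
#'   U are canonicalized (upper case, U -> T)
#' @param biotinylated logical metadata flag
#' @return a \linkS4class{DegenerateOligo}
#' @examples
#' degenerateOligo("F11", "MAGTGATATGGACTAWGTGG")
#' @export
degenerateOligo <- function(name, sequence, biotinylated = FALSE) {
  new("DegenerateOligo", name = as.character(name),
      sequence = .canonSeq(sequence), biotinylated = isTRUE(biotinylated))
}

.asOligo <- function(x, name = "oligo") {
  if (is(x, "DegenerateOligo")) x else degenerateOligo(name, x)
}

#' @describeIn degenerateOligo sequence accessor
#' @param x a \code{DegenerateOligo}
#' @export
oligoSequence <- function(x) .asOligo(x)@sequence

#' @describeIn degenerateOligo name accessor
#' @export
oligoName <- function(x) .asOligo(x)@name

setMethod("show", "DegenerateOligo", function(object) {
  cat(sprintf("DegenerateOligo %s: 5'-%s-3' (%d nt, degeneracy %d%s)\n",
              object@name, object@sequence, nchar(object@sequence),
              oligoDegeneracy(object),
              if (object@biotinylated) ", biotinylated" else ""))
})

#' Degeneracy of an oligo
#'
#' Product of the per-position allowed-base counts.
#'
#' @param oligo a \linkS4class{DegenerateOligo} or sequence string
#' @return integer degeneracy (>= 1)
#' @export
oligoDegeneracy <- function(oligo) {
  mask <- .encodeSeq(oligoSequence(oligo))
  as.integer(prod(.maskWidth(mask)))
}

#' Expand a degenerate oligo into its concrete sequences
#'
#' @param oligo a \linkS4class{DegenerateOligo} or sequence string
#' @param cap maximum degeneracy to expand (guards combinatorial blow-up)
#' @return character vector of all concrete expansions (sorted); its length
#'   equals the degeneracy
#' @examples
#' expandDegenerate("MAGT")   # "AAGT" "CAGT"
#' @export
expandDegenerate <- function(oligo, cap = 4096L) {
  mask <- .encodeSeq(oligoSequence(oligo))
  deg <- prod(.maskWidth(mask))
  if (deg > cap)
    stop("degeneracy ", deg, " exceeds cap ", cap)
  sets <- lapply(mask, function(m) .BASES[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L])
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = ""))
}

#' IUPAC-aware reverse complement
#'
#' Position-wise IUPAC complement (A<->T, C<->G, M<->K, R<->Y, W<->W, S<->S,
#' B<->V, D<->H, N<->N) followed by reversal; an involution.
#'
#' @param x a \linkS4class{DegenerateOligo} or a sequence string
#' @return object of the same kind as the input
#' @importFrom Biostrings reverseComplement DNAString
#' @export
revComp <- function(x) {
  if (is(x, "DegenerateOligo")) {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x@sequence)))
    new("DegenerateOligo", name = x@name, sequence = s,
        biotinylated = x@biotinylated)
  } else {
    mask <- .encodeSeq(x)  # validates and canonicalizes
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(.decodeMask(mask))))
  }
}

#' Degenerate-aware mismatch count against an equal-length window
#'
#' A position mismatches when the (concrete) window base is not in the
#' oligo's allowed-base set, so degenerate positions match any of their
#' bases.
#'
#' @param oligo \linkS4class{DegenerateOligo} or sequence string
#' @param window concrete sequence of the same length
#' @return non-negative integer
#' @export
mismatchCount <- function(oligo, window) {
  o <- .encodeSeq(oligoSequence(oligo))
  w <- .encodeSeq(window)
  if (length(o) != length(w))
    stop("oligo and window must have equal length")
  if (!.isConcreteSeq(window))
    stop("window must be a concrete (A/C/G/T) sequence")
  mm_count_c(o, w)
}

#' Minimum mismatches of an oligo over all windows of a target
#'
#' Scans every window of the oligo's length along the target (and along its
#' reverse complement when \code{strands = "both"}) and returns the minimum
#' degenerate-aware mismatch count.  Ties are broken to the smallest start,
#' and the given strand wins over the reverse strand.
#'
#' @param oligo \linkS4class{DegenerateOligo} or sequence string
#' @param target concrete sequence, at least as long as the oligo
#' @param strands scan the given strand only, or both
#' @return list with \code{mismatches}, 0-based \code{start} (window
#'   position on the given target), and \code{strand} ("given"/"reverse")
#' @export
minMismatches <- function(oligo, target, strands = c("given", "both")) {
  strands <- match.arg(strands)
  o <- .encodeSeq(oligoSequence(oligo))
  if (!.isConcreteSeq(target))
    stop("target must be a concrete (A/C/G/T) sequence")
  t <- .encodeSeq(target)
  if (length(t) < length(o)) stop("target shorter than oligo")
  hit <- scan_min_c(o, t)
  hit$strand <- "given"
  if (strands == "both") {
    orc <- .encodeSeq(revComp(oligoSequence(oligo)))
    hit2 <- scan_min_c(orc, t)
    if (hit2$mismatches < hit$mismatches) {
      hit2$strand <- "reverse"
      hit <- hit2
    }
  }
  hit
}

#' Global pairwise identity of two concrete sequences
#'
#' Needleman-Wunsch global alignment with configurable scores; identity is
#' the number of matching positions divided by the alignment length (gaps
#' included), as a percentage.  Symmetric in its arguments.
#'
#' @param a,b concrete nucleotide sequences
#' @param match,mismatch,gapOpening,gapExtension alignment scores; the
#'   defaults are match +1, mismatch -1, gap open -2, gap extend -1
#'   (penalties given as positive numbers to \code{gapOpening}/
#'   \code{gapExtension})
#' @return identity percentage in [0, 100]
#' @importFrom Biostrings pairwiseAlignment nucleotideSubstitutionMatrix
#'   nmatch alignedPattern
#' @export
pairwiseIdentity <- function(a, b, match = 1, mismatch = -1,
                             gapOpening = 2, gapExtension = 1) {
  a <- .canonSeq(a); b <- .canonSeq(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = sub,
                                       gapOpening = gapOpening,
                                       gapExtension = gapExtension)
  alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / alnLen
}
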