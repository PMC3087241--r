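# IUPAC nucleotide algebra: bitmask encoding shared with the C++ scan core.
# A=1, C=2, G=4, T=8; ambiguity codes are bitwise ORs of their base sets.

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

.MASK_CODE <- character(15L)
.MASK_CODE[.IUPAC_MASK] <- names(.IUPAC_MASK)

.BASES <- c("A", "C", "G", "T")

# Canonical form: upper case, U mapped to T.
.canonSeq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

# Encode one sequence to its bitmask vector; errors name the first offending
# position (1-based).
.encodeSeq <- function(x) {
  chars <- strsplit(.canonSeq(x), "", fixed = TRUE)[[1L]]
  m <- .IUPAC_MASK[chars]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    stop("invalid IUPAC character '", chars[bad], "' at position ", bad,
         call. = FALSE)
  }
  unname(m)
}

.decodeMask <- function(mask) paste(.MASK_CODE[mask], collapse = "")

# Number of concrete bases allowed at each position.
.maskWidth <- function(mask) {
  vapply(mask, function(m) sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L), integer(1))
}

.isConcreteSeq <- function(x) {
  grepl("^[ACGT]+$", .canonSeq(x))
}
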