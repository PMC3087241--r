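# StrainCollection accessors and group algebra.

#' @describeIn strainCollection strain ids
#' @param x a \linkS4class{StrainCollection}
#' @export
strainIds <- function(x) names(x@sequences)

#' @describeIn strainCollection sequences as a named character vector
#' @export
strainSeqs <- function(x) setNames(as.character(x@sequences), strainIds(x))

#' @describeIn strainCollection number of strains
#' @export
nStrains <- function(x) length(x@sequences)

#' @describeIn strainCollection group label -> member strain ids
#' @export
groupIndex <- function(x) {
  labs <- sort(unique(unlist(x@groups, use.names = FALSE)))
  setNames(lapply(labs, function(g) {
    names(x@groups)[vapply(x@groups, function(gs) g %in% gs, logical(1))]
  }), labs)
}

#' @describeIn strainCollection labels of all groups
#' @export
groupNames <- function(x) sort(unique(unlist(x@groups, use.names = FALSE)))

#' @describeIn strainCollection member strain ids of one group
#' @param group group label
#' @export
groupMembers <- function(x, group) {
  idx <- groupIndex(x)
  if (!group %in% names(idx)) stop("unknown group: ", group)
  idx[[group]]
}

# Groups nested-related to `group`: groups whose member set is a subset or
# superset of the target's (probes of nested groups coexist in one panel, so
# their members are excluded from each other's non-target sets).
.relatedGroups <- function(x, group) {
  idx <- groupIndex(x)
  tgt <- idx[[group]]
  related <- vapply(idx, function(m) all(m %in% tgt) || all(tgt %in% m),
                    logical(1))
  names(idx)[related]
}

# Strain ids outside the target group and outside any nested-related group.
.nontargetIds <- function(x, group) {
  idx <- groupIndex(x)
  excl <- unique(unlist(idx[.relatedGroups(x, group)], use.names = FALSE))
  setdiff(strainIds(x), excl)
}

setMethod("show", "StrainCollection", function(object) {
  gi <- groupIndex(object)
  cat(sprintf("StrainCollection: %d strains, %d groups\n",
              nStrains(object), length(gi)))
  w <- nchar(as.character(object@sequences))
  cat(sprintf("  marker lengths: %d-%d nt\n", min(w), max(w)))
  if (length(gi)) {
    sizes <- vapply(gi, length, integer(1))
    cat("  groups: ",
        paste(sprintf("%s(%d)", names(gi), sizes), collapse = ", "), "\n",
        sep = "")
  }
  ungrouped <- sum(vapply(object@groups, length, integer(1)) == 0L)
  if (ungrouped) cat(sprintf("  %d strains not targeted by any group\n", ungrouped))
})

# Encoded sequences (bitmask vectors), forward and reverse complement, for
# the C scan core.  Computed once per collection use.
.encodeCollection <- function(x) {
  seqs <- strainSeqs(x)
  fwd <- lapply(seqs, .encodeSeq)
  rc <- lapply(seqs, function(s) .encodeSeq(revComp(s)))
  list(fwd = unname(fwd), rc = unname(rc), ids = names(seqs))
}
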