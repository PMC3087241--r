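# Detection frequencies, per-habitat richness, and sympatry-allopatry
# (Venn) co-occurrence analysis of binary detection matrices.

.checkBinary <- function(Y) {
  Y <- as.matrix(Y)
  if (!length(Y)) stop("empty matrix")
  if (!all(Y %in% c(0, 1))) stop("matrix is not binary (0/1)")
  storage.mode(Y) <- "integer"
  Y
}

#' Detection frequency per probe group
#'
#' @param Y binary habitats x groups matrix
#' @return named percentages (100 x column mean)
#' @export
detectionFrequency <- function(Y) {
  Y <- .checkBinary(Y)
  100 * colMeans(Y)
}

#' Mean and standard deviation of per-habitat group richness
#'
#' @param Y binary habitats x groups matrix
#' @param sdType sample (n-1 denominator, default) or population SD
#' @return list with mean and sd of the per-habitat row sums
#' @export
richnessStats <- function(Y, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  Y <- .checkBinary(Y)
  rs <- rowSums(Y)
  s <- if (length(rs) > 1L) sd(rs) else 0
  if (sdType == "population")
    s <- sqrt(mean((rs - mean(rs))^2))
  list(mean = mean(rs), sd = s)
}

#' Sympatry-allopatry / Venn co-occurrence analysis
#'
#' Counts, for a chosen subset of groups, every presence/absence
#' combination (Venn cell) across habitats, the pairwise co-occurrence
#' counts, and flags pairs that never co-occur (complete niche separation
#' candidates).  Per-group detection frequencies and per-habitat richness
#' refer to the full matrix.
#'
#' @param Y binary habitats x groups matrix
#' @param subset group (column) labels to analyse jointly; 1 to 8 groups
#' @return a \linkS4class{CooccurrenceReport}
#' @export
cooccurrence <- function(Y, subset = colnames(Y)) {
  Y <- .checkBinary(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("G", seq_len(ncol(Y)))
  unknown <- setdiff(subset, colnames(Y))
  if (length(unknown)) stop("unknown group label: ",
                            paste(unknown, collapse = ", "))
  k <- length(subset)
  if (k < 1L || k > 8L) stop("subset size must be between 1 and 8")
  S <- Y[, subset, drop = FALSE]
  n <- nrow(S)

  patterns <- apply(S, 1L, paste, collapse = "")
  allPat <- apply(expand.grid(rep(list(c(0L, 1L)), k))[, k:1, drop = FALSE],
                  1L, paste, collapse = "")
  counts <- table(factor(patterns, levels = allPat))
  cells <- data.frame(pattern = allPat, count = as.integer(counts),
                      percent = 100 * as.integer(counts) / n,
                      row.names = NULL)

  pairCounts <- crossprod(S)
  never <- pairCounts == 0L
  diag(never) <- FALSE

  rich <- richnessStats(Y)
  new("CooccurrenceReport", frequencies = detectionFrequency(Y),
      vennCells = cells, pairwiseCounts = pairCounts,
      neverCooccur = never, richnessMean = rich$mean,
      richnessSD = rich$sd, nHabitats = nrow(Y), subset = subset)
}

setMethod("show", "CooccurrenceReport", function(object) {
  cat(sprintf("CooccurrenceReport: %d habitats, subset {%s}\n",
              object@nHabitats, paste(object@subset, collapse = ", ")))
  cat(sprintf("  richness per habitat: %.1f +/- %.1f groups\n",
              object@richnessMean, object@richnessSD))
  occupied <- object@vennCells[object@vennCells$count > 0, ]
  print(occupied, row.names = FALSE)
  nc <- object@neverCooccur
  if (any(nc)) {
    idx <- which(nc & upper.tri(nc), arr.ind = TRUE)
    pairs <- apply(idx, 1L, function(i)
      paste(rownames(nc)[i[1L]], colnames(nc)[i[2L]], sep = "/"))
    cat("  never co-occur: ", paste(pairs, collapse = ", "), "\n", sep = "")
  }
})
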