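# Minimal base-graphics views of the main results: an ordination biplot,
# a gradient-sorted detection heatmap, and a rectangle co-occurrence
# (Venn-style) panel.

#' Ordination biplot
#'
#' Sites as points, species (probe groups) as labelled triangles, and
#' environmental variables as arrows (scaled into the plot range).
#'
#' @param ord an \linkS4class{OrdinationResult}
#' @param axes which two axes to draw
#' @param ... passed to \code{plot}
#' @return invisibly, NULL
#' @importFrom graphics points text arrows abline
#' @export
plotOrdination <- function(ord, axes = c(1, 2), ...) {
  st <- siteScores(ord)
  sp <- speciesScores(ord)
  if (ncol(st) < max(axes)) stop("not enough axes")
  xl <- range(c(st[, axes[1]], sp[, axes[1]]))
  yl <- range(c(st[, axes[2]], sp[, axes[2]]))
  plot(st[, axes[1]], st[, axes[2]], pch = 1, col = "grey40",
       xlab = colnames(st)[axes[1]], ylab = colnames(st)[axes[2]],
       xlim = xl, ylim = yl, ...)
  abline(h = 0, v = 0, lty = 3, col = "grey70")
  points(sp[, axes[1]], sp[, axes[2]], pch = 17, col = "firebrick")
  text(sp[, axes[1]], sp[, axes[2]], rownames(sp), pos = 3, cex = 0.8,
       col = "firebrick")
  bp <- biplotScores(ord)
  if (nrow(bp)) {
    sc <- 0.9 * min(max(abs(xl)), max(abs(yl)))
    arrows(0, 0, sc * bp[, axes[1]], sc * bp[, axes[2]], length = 0.08,
           col = "navy")
    text(sc * bp[, axes[1]], sc * bp[, axes[2]], rownames(bp), pos = 4,
         cex = 0.8, col = "navy")
  }
  invisible(NULL)
}

#' Gradient-sorted detection heatmap
#'
#' Habitats (rows of the binary or ordinal matrix) are sorted by an
#' environmental variable (typically pH) and drawn as grey-scale tiles:
#' white = no detection, light/mid/black = increasing signal class.
#'
#' @param x a \linkS4class{DetectionMatrix} or binary matrix
#' @param sortBy numeric vector (one value per habitat) to sort rows by,
#'   e.g. the habitats' pH; NULL keeps the given order
#' @param ... passed to \code{image}
#' @return invisibly, the row order used
#' @importFrom graphics image axis
#' @export
plotDetectionHeatmap <- function(x, sortBy = NULL, ...) {
  m <- if (is(x, "DetectionMatrix")) {
    matrix(match(classMatrix(x), .SIGNAL_CLASSES) - 1L,
           nrow = nrow(classMatrix(x)), dimnames = dimnames(classMatrix(x)))
  } else {
    storage.mode(x) <- "integer"
    x * 3L
  }
  ord <- if (is.null(sortBy)) seq_len(nrow(m)) else order(sortBy)
  m <- m[ord, , drop = FALSE]
  image(seq_len(nrow(m)), seq_len(ncol(m)), m,
        col = c("white", "grey80", "grey45", "black"),
        zlim = c(0, 3), xlab = "habitats (sorted)", ylab = "", axes = FALSE,
        ...)
  axis(2, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
       cex.axis = 0.7)
  axis(1)
  invisible(ord)
}

#' Rectangle co-occurrence plot
#'
#' One rectangle per group with area proportional to its detection
#' frequency, annotated with the pairwise co-occurrence counts of the
#' report's subset.
#'
#' @param rep a \linkS4class{CooccurrenceReport}
#' @param ... passed to \code{plot}
#' @return invisibly, NULL
#' @importFrom graphics rect text plot.new plot.window title
#' @export
plotCooccurrence <- function(rep, ...) {
  freq <- rep@frequencies[rep@subset]
  k <- length(freq)
  plot.new()
  plot.window(xlim = c(0, k), ylim = c(0, 1.2))
  side <- sqrt(freq / 100)
  for (i in seq_len(k)) {
    rect(i - 1 + (1 - side[i] * 0.9) / 2, 0.1,
         i - 1 + (1 + side[i] * 0.9) / 2, 0.1 + side[i] * 0.9,
         col = "grey85", border = "grey30")
    text(i - 0.5, 0.05, sprintf("%s\n%.0f%%", rep@subset[i], freq[i]),
         cex = 0.8, xpd = NA)
  }
  pairs <- which(upper.tri(rep@pairwiseCounts), arr.ind = TRUE)
  lab <- apply(pairs, 1, function(ij)
    sprintf("%s/%s: %d", rownames(rep@pairwiseCounts)[ij[1]],
            colnames(rep@pairwiseCounts)[ij[2]],
            rep@pairwiseCounts[ij[1], ij[2]]))
  text(k / 2, 1.12, paste(lab, collapse = "   "), cex = 0.7)
  title(main = sprintf("co-occurrence over %d habitats", rep@nHabitats))
  invisible(NULL)
}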