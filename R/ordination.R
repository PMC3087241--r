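# Correspondence-analysis family ordination (CA/CCA, PCA/RDA) with the
# weighted-SVD algorithm; deterministic up to axis sign, with the sign
# fixed so the largest-magnitude species score on each axis is positive.

.checkResponse <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("response matrix must be non-negative")
  zr <- rowSums(Y) == 0
  zc <- colSums(Y) == 0
  if (any(zr))
    stop("all-zero response rows: ",
         paste(rownames(Y)[zr] %||% which(zr), collapse = ", "),
         " (drop them explicitly, e.g. with dropEmpty())")
  if (any(zc))
    stop("all-zero response columns: ",
         paste(colnames(Y)[zc] %||% which(zc), collapse = ", "),
         " (drop them explicitly, e.g. with dropEmpty())")
  Y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop all-zero rows and columns from a matrix
#'
#' The explicit drop step required before correspondence analysis of a
#' detection matrix (habitats without any detection, probes never
#' positive).
#'
#' @param Y matrix
#' @return matrix without all-zero rows/columns; the removed names are in
#'   attributes \code{dropped_rows} / \code{dropped_cols}
#' @export
dropEmpty <- function(Y) {
  Y <- as.matrix(Y)
  zr <- rowSums(Y != 0) == 0
  zc <- colSums(Y != 0) == 0
  out <- Y[!zr, !zc, drop = FALSE]
  attr(out, "dropped_rows") <- rownames(Y)[zr] %||% which(zr)
  attr(out, "dropped_cols") <- colnames(Y)[zc] %||% which(zc)
  out
}

# chi-square standardized residual matrix of the row/column-mass model
.caCore <- function(Y) {
  Y <- .checkResponse(Y)
  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P)
  cc <- colSums(P)
  Qbar <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  list(Qbar = Qbar, r = r, c = cc, totalInertia = sum(Qbar^2), grandTotal = tot)
}

# weighted centering (and unit-variance scaling) of an explanatory matrix,
# already multiplied by sqrt(weights) for use in the weighted projection
.weightEnv <- function(X, w, standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X))
    stop("environmental matrix has missing values; apply resolveMissing()")
  mu <- colSums(X * w) / sum(w)
  Xc <- sweep(X, 2L, mu)
  if (standardize) {
    sdw <- sqrt(colSums(w * Xc^2) / sum(w))
    sdw[sdw == 0] <- 1
    Xc <- sweep(Xc, 2L, sdw, "/")
  }
  list(Xc = Xc, Xw = Xc * sqrt(w))
}

.qrBasis <- function(Xw, tol = 1e-9) {
  qrx <- qr(Xw, tol = tol)
  if (qrx$rank < ncol(Xw)) {
    drop <- colnames(Xw)[qrx$pivot[(qrx$rank + 1L):ncol(Xw)]] %||%
            qrx$pivot[(qrx$rank + 1L):ncol(Xw)]
    stop("explanatory matrix is rank deficient; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  qr.Q(qrx)
}

.fixSigns <- function(species, sites, biplot) {
  for (k in seq_len(ncol(species))) {
    j <- which.max(abs(species[, k]))
    if (species[j, k] < 0) {
      species[, k] <- -species[, k]
      sites[, k] <- -sites[, k]
      if (ncol(biplot)) biplot[, k] <- -biplot[, k]
    }
  }
  list(species = species, sites = sites, biplot = biplot)
}

.axisNames <- function(k, prefix) {
  if (k == 0L) character(0) else paste0(prefix, seq_len(k))
}

#' Ordination of a detection or abundance matrix
#'
#' \code{method = "ca"}/\code{"cca"}: correspondence analysis of the
#' chi-square standardized residuals of the row/column-mass model; CCA
#' constrains the solution to the column space of the (weighted,
#' standardized) environmental matrix by weighted least squares before the
#' singular value decomposition.  \code{"pca"}/\code{"rda"}: PCA of the
#' centred response / of its fitted values from the multivariate regression
#' on the explanatory matrix.  RDA with a zero-column explanatory matrix
#' reduces to PCA.
#'
#' The default scaling is species-focused: species scores are scaled by the
#' square roots of the eigenvalues, site scores are left unscaled.
#'
#' @param Y response matrix (habitats x probe groups; non-negative for
#'   ca/cca, no all-zero rows or columns - see \code{\link{dropEmpty}})
#' @param X explanatory (environmental) matrix or data.frame, standardized
#'   internally; NULL for unconstrained methods
#' @param method one of \code{"cca"}, \code{"rda"}, \code{"ca"},
#'   \code{"pca"}
#' @param direction \code{"env_explains_groups"} uses Y as response and X
#'   as explanatory; \code{"groups_explain_env"} swaps the roles (the
#'   inverted design in which environmental characteristics are the
#'   explained variables); recorded in the result metadata
#' @param scaleResponse standardize response columns (rda/pca only)
#' @return an \linkS4class{OrdinationResult}
#' @export
ordinate <- function(Y, X = NULL, method = c("cca", "rda", "ca", "pca"),
                     direction = c("env_explains_groups",
                                   "groups_explain_env"),
                     scaleResponse = FALSE) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  if (direction == "groups_explain_env") {
    if (is.null(X)) stop("direction inversion needs both matrices")
    tmp <- Y; Y <- X; X <- tmp
  }
  if (method %in% c("ca", "pca")) X <- NULL
  if (method %in% c("cca", "rda") && is.null(X))
    stop("constrained methods need an explanatory matrix")
  if (!is.null(X) && ncol(as.matrix(X)) == 0L && method == "rda")
    method <- "pca"

  if (method %in% c("ca", "cca")) {
    core <- .caCore(Y)
    if (method == "ca") {
      sv <- svd(core$Qbar)
      keep <- which(sv$d^2 > 1e-12)
      d <- sv$d[keep]
      species <- sweep(sv$v[, keep, drop = FALSE], 1L, sqrt(core$c), "/")
      sites <- sweep(sv$u[, keep, drop = FALSE], 1L, sqrt(core$r), "/")
      species <- sweep(species, 2L, d, "*")   # species-focused scaling
      biplot <- matrix(numeric(0), nrow = 0, ncol = length(keep))
      cf <- NA_real_
    } else {
      env <- .weightEnv(X, core$r)
      Q0 <- .qrBasis(env$Xw)
      fit <- Q0 %*% (t(Q0) %*% core$Qbar)
      sv <- svd(fit)
      keep <- which(sv$d^2 > 1e-12)
      keep <- head(keep, ncol(Q0))
      d <- sv$d[keep]
      species <- sweep(sv$v[, keep, drop = FALSE], 1L, sqrt(core$c), "/")
      sites <- sweep(sv$u[, keep, drop = FALSE], 1L, sqrt(core$r), "/")
      species <- sweep(species, 2L, d, "*")
      biplot <- .wcorMatrix(env$Xc, sites, core$r)
      cf <- sum(d^2) / core$totalInertia
    }
    tin <- core$totalInertia
  } else {
    Yc <- scale(as.matrix(Y), center = TRUE, scale = scaleResponse)
    n <- nrow(Yc)
    tin <- sum(Yc^2) / (n - 1)
    if (method == "pca") {
      sv <- svd(Yc / sqrt(n - 1))
      keep <- which(sv$d^2 > 1e-12)
      d <- sv$d[keep]
      species <- sv$v[, keep, drop = FALSE]
      sites <- sv$u[, keep, drop = FALSE] * sqrt(n - 1)
      species <- sweep(species, 2L, d, "*")
      biplot <- matrix(numeric(0), nrow = 0, ncol = length(keep))
      cf <- NA_real_
    } else {
      env <- .weightEnv(X, rep(1 / n, n))
      Q0 <- .qrBasis(env$Xc)   # ordinary least squares basis
      fit <- Q0 %*% (t(Q0) %*% Yc)
      sv <- svd(fit / sqrt(n - 1))
      keep <- which(sv$d^2 > 1e-12)
      keep <- head(keep, ncol(Q0))
      d <- sv$d[keep]
      species <- sv$v[, keep, drop = FALSE]
      sites <- sv$u[, keep, drop = FALSE] * sqrt(n - 1)
      species <- sweep(species, 2L, d, "*")
      biplot <- .wcorMatrix(env$Xc, sites, rep(1 / n, n))
      cf <- sum(d^2) / tin
    }
  }
  fx <- .fixSigns(species, sites, biplot)
  k <- length(d)
  prefix <- switch(method, ca = "CA", cca = "CCA", pca = "PC", rda = "RDA")
  colnames(fx$species) <- colnames(fx$sites) <- .axisNames(k, prefix)
  rownames(fx$species) <- colnames(as.matrix(Y))
  rownames(fx$sites) <- rownames(as.matrix(Y))
  if (nrow(fx$biplot)) {
    colnames(fx$biplot) <- .axisNames(k, prefix)
    rownames(fx$biplot) <- colnames(as.matrix(X))
  }
  new("OrdinationResult", method = toupper(method), eigenvalues = d^2,
      totalInertia = tin, constrainedFraction = cf,
      siteScores = fx$sites, speciesScores = fx$species,
      biplotScores = fx$biplot, scaling = "species",
      metadata = list(direction = direction))
}

# weighted correlations of environmental columns with site scores
.wcorMatrix <- function(Xc, sites, w) {
  w <- w / sum(w)
  out <- matrix(NA_real_, nrow = ncol(Xc), ncol = ncol(sites))
  for (j in seq_len(ncol(Xc))) {
    xj <- Xc[, j] - sum(w * Xc[, j])
    for (k in seq_len(ncol(sites))) {
      sk <- sites[, k] - sum(w * sites[, k])
      den <- sqrt(sum(w * xj^2) * sum(w * sk^2))
      out[j, k] <- if (den > 0) sum(w * xj * sk) / den else 0
    }
  }
  out
}

#' @describeIn ordinate eigenvalue accessor
#' @param object an \linkS4class{OrdinationResult}
#' @export
ordEigenvalues <- function(object) object@eigenvalues

#' @describeIn ordinate total inertia / variance accessor
#' @export
totalInertia <- function(object) object@totalInertia

#' @describeIn ordinate constrained-variance fraction accessor
#' @export
constrainedFraction <- function(object) object@constrainedFraction

#' @describeIn ordinate site score accessor
#' @export
siteScores <- function(object) object@siteScores

#' @describeIn ordinate species score accessor
#' @export
speciesScores <- function(object) object@speciesScores

#' @describeIn ordinate environmental biplot score accessor
#' @export
biplotScores <- function(object) object@biplotScores

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult (%s): %d axes, total inertia %.4f\n",
              object@method, length(object@eigenvalues),
              object@totalInertia))
  if (!is.na(object@constrainedFraction))
    cat(sprintf("  constrained fraction: %.3f\n",
                object@constrainedFraction))
  ev <- head(object@eigenvalues, 4L)
  cat("  eigenvalues: ", paste(sprintf("%.4f", ev), collapse = ", "),
      if (length(object@eigenvalues) > 4L) ", ..." else "", "\n", sep = "")
})
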