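# Monte Carlo permutation tests (unrestricted permutation of the candidate
# variable's habitat rows) and permutation forward selection of
# environmental variables, for both the CCA (weighted) and RDA
# (unweighted) frameworks.  The p-value uses the add-one convention
# (1 + b) / (1 + m), so it never returns 0 and its floor at m permutations
# is 1 / (m + 1).

# Shared state for one (Y, X_selected) configuration.
.permSetup <- function(Y, Xsel, method) {
  if (method == "cca") {
    core <- .caCore(Y)
    resp <- core$Qbar
    w <- core$r
  } else {
    resp <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
    w <- rep(1 / nrow(resp), nrow(resp))
  }
  Q0 <- NULL
  q <- 0L
  if (!is.null(Xsel) && ncol(as.matrix(Xsel)) > 0L) {
    env <- .weightEnv(as.matrix(Xsel), w)
    Q0 <- .qrBasis(env$Xw)
    q <- ncol(Q0)
  }
  Yr <- if (is.null(Q0)) resp else resp - Q0 %*% (t(Q0) %*% resp)
  list(Yr = Yr, SSYr = sum(Yr^2), w = w, Q0 = Q0, q = q, n = nrow(resp))
}

# Orthonormal basis tolerating rank deficiency (drops dependent columns
# instead of erroring; used for whole-model fits, not for user-facing
# ordination where collinearity is reported).
.qrBasisTolerant <- function(Xw, tol = 1e-9) {
  qrx <- qr(Xw, tol = tol)
  qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
}

# Constrained-variance fraction of Y on X (no scores, no SVD: the
# constrained inertia is the squared norm of the projected response).
.constrFraction <- function(Y, X, method) {
  if (method == "cca") {
    core <- .caCore(Y)
    env <- .weightEnv(as.matrix(X), core$r)
    Q0 <- .qrBasisTolerant(env$Xw)
    sum((t(Q0) %*% core$Qbar)^2) / core$totalInertia
  } else {
    Yc <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
    env <- .weightEnv(as.matrix(X), rep(1 / nrow(Yc), nrow(Yc)))
    Q0 <- .qrBasisTolerant(env$Xc)
    sum((t(Q0) %*% Yc)^2) / sum(Yc^2)
  }
}

#' Adjusted constrained-variance fraction (adjusted R-squared)
#'
#' For RDA the closed-form (Ezekiel) adjustment; for CCA the
#' permutation-based adjustment (the expectation of the constrained
#' fraction under row permutation of the explanatory matrix), consuming
#' the current RNG stream.
#'
#' @param Y response matrix
#' @param X explanatory matrix/data.frame
#' @param method \code{"cca"} or \code{"rda"}
#' @param nPermAdj permutations for the CCA adjustment
#' @return adjusted fraction (can be negative)
#' @export
adjustedR2 <- function(Y, X, method = c("rda", "cca"), nPermAdj = 99L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  R2 <- .constrFraction(Y, X, method)
  n <- nrow(X)
  if (method == "rda") {
    m <- qr(scale(X, center = TRUE, scale = FALSE))$rank
    1 - (1 - R2) * (n - 1) / (n - 1 - m)
  } else {
    R2p <- vapply(seq_len(nPermAdj), function(b)
      .constrFraction(Y, X[sample.int(n), , drop = FALSE], method),
      numeric(1))
    1 - (1 - R2) / (1 - mean(R2p))
  }
}

# candidate column -> residualized unit of analysis in the weighted space
.residCandidate <- function(z, setup) {
  zw <- sqrt(setup$w) * (z - sum(setup$w * z) / sum(setup$w))
  zr <- if (is.null(setup$Q0)) zw else zw - setup$Q0 %*% (t(setup$Q0) %*% zw)
  drop(zr)
}

# pseudo-F of a residualized candidate against the residual response
.pseudoF <- function(zr, setup) {
  den <- sum(zr^2)
  added <- sum((crossprod(setup$Yr, zr))^2) / den
  dfres <- setup$n - 1L - setup$q - 1L
  resid <- setup$SSYr - added
  list(F = added / (resid / dfres), added = added)
}

# Core test, consuming the current RNG stream (callers fix the seed).
.permTestCore <- function(Y, Xsel, z, nPerm, method, setup = NULL) {
  if (is.null(setup)) setup <- .permSetup(Y, Xsel, method)
  if (stats::var(z) == 0) stop("constant candidate variable")
  zr <- .residCandidate(z, setup)
  if (sum(zr^2) < 1e-10 * sum(z^2) / length(z) || sum(zr^2) < 1e-12)
    return(list(F = NA_real_, added = 0, p = NA_real_, collinear = TRUE))
  obs <- .pseudoF(zr, setup)
  n <- setup$n
  perms <- matrix(0L, nrow = n, ncol = nPerm)
  for (b in seq_len(nPerm)) perms[, b] <- sample.int(n)
  Zp <- matrix(z[perms], nrow = n)
  wm <- colSums(setup$w * Zp) / sum(setup$w)
  Zw <- sqrt(setup$w) * sweep(Zp, 2L, wm)
  Zr <- if (is.null(setup$Q0)) Zw
        else Zw - setup$Q0 %*% (t(setup$Q0) %*% Zw)
  den <- colSums(Zr^2)
  ok <- den > 1e-12
  addedB <- rep(NA_real_, nPerm)
  addedB[ok] <- colSums((crossprod(setup$Yr, Zr[, ok, drop = FALSE]))^2) /
    den[ok]
  dfres <- n - 1L - setup$q - 1L
  FB <- addedB / ((setup$SSYr - addedB) / dfres)
  b <- sum(FB >= obs$F - 1e-12, na.rm = TRUE)
  list(F = obs$F, added = obs$added, p = (1 + b) / (1 + nPerm),
       collinear = FALSE)
}

#' Monte Carlo permutation test for one environmental variable
#'
#' Tests the added constrained variance of a candidate variable given an
#' already-selected explanatory set, by unrestricted permutation of the
#' candidate's habitat rows (raw-data scheme).  The statistic is the
#' pseudo-F: added constrained variance over residual variance (per
#' residual degree of freedom).
#'
#' @param Y response matrix (see \code{\link{ordinate}})
#' @param Xsel matrix/data.frame of already-selected variables (NULL for
#'   none)
#' @param candidate numeric vector, the candidate variable (habitat order
#'   matching Y)
#' @param nPerm number of permutations (>= 1); the smallest attainable
#'   p-value is \code{1 / (nPerm + 1)}
#' @param seed integer seed for the permutation stream
#' @param method \code{"cca"} (weighted, unimodal) or \code{"rda"}
#'   (linear)
#' @return list with \code{F}, \code{added} (added constrained variance),
#'   \code{p}, \code{nPerm}
#' @export
permutationTest <- function(Y, Xsel, candidate, nPerm = 999L, seed = 1L,
                            method = c("cca", "rda")) {
  method <- match.arg(method)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  res <- withr::with_seed(seed,
    .permTestCore(Y, Xsel, as.numeric(candidate), as.integer(nPerm), method))
  if (isTRUE(res$collinear))
    stop("candidate is collinear with the selected variables")
  res$nPerm <- as.integer(nPerm)
  res
}

#' Permutation forward selection of environmental variables
#'
#' Repeatedly adds the candidate with the largest added explained variance
#' among those whose permutation p-value (adjusted across the candidates
#' tested in the step; Holm by default) is below \code{alpha}; stops when
#' no candidate qualifies, or — with the global stop active — once the
#' selected model's adjusted constrained fraction reaches that of the
#' model containing all candidates (guards against stepwise overselection
#' of noise variables).  Candidates collinear with the selected set (e.g.
#' a duplicated variable) are skipped, so exactly one copy of a duplicated
#' informative variable can enter.  Fully deterministic given the seed.
#'
#' @param Y response matrix
#' @param X data.frame/matrix of candidate environmental variables
#' @param alpha entry threshold on the (adjusted) permutation p-value
#' @param nPerm permutations per entry test
#' @param seed integer seed
#' @param method \code{"cca"} or \code{"rda"}
#' @param adjust per-step multiplicity adjustment over the candidates
#'   tested (\code{"holm"} or \code{"none"})
#' @param globalStop apply the global adjusted-R2 stopping rule (only
#'   meaningful with >= 2 candidates)
#' @return a \linkS4class{ForwardSelectionResult}
#' @export
forwardSelect <- function(Y, X, alpha = 0.05, nPerm = 999L, seed = 1L,
                          method = c("cca", "rda"),
                          adjust = c("holm", "none"), globalStop = TRUE) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  X <- as.data.frame(X)
  if (!ncol(X)) stop("at least one candidate variable is required")
  vars <- colnames(X)
  selected <- character(0)
  selRows <- list()
  lastP <- setNames(rep(NA_real_, length(vars)), vars)
  withr::with_seed(seed, {
    globalAdjR2 <- if (globalStop && length(vars) >= 2L)
      adjustedR2(Y, X, method) else Inf
    repeat {
      remaining <- setdiff(vars, selected)
      if (!length(remaining)) break
      if (length(selected) &&
          adjustedR2(Y, X[, selected, drop = FALSE], method) >= globalAdjR2)
        break
      Xsel <- if (length(selected)) X[, selected, drop = FALSE] else NULL
      setup <- .permSetup(Y, Xsel, method)
      tests <- lapply(remaining, function(v)
        .permTestCore(Y, Xsel, as.numeric(X[[v]]), as.integer(nPerm),
                      method, setup = setup))
      names(tests) <- remaining
      p <- vapply(tests, function(t) t$p %||% NA_real_, numeric(1))
      added <- vapply(tests, `[[`, numeric(1), "added")
      collinear <- vapply(tests, function(t) isTRUE(t$collinear), logical(1))
      lastP[remaining] <- p
      padj <- p
      padj[!collinear] <- p.adjust(p[!collinear], method = adjust)
      eligible <- !collinear & !is.na(padj) & padj < alpha
      # global ceiling (never applied to the first variable): a candidate
      # whose inclusion pushes the cumulative adjusted R2 beyond the
      # all-candidate model's cannot enter
      if (length(selected) && is.finite(globalAdjR2)) {
        for (v in remaining[eligible]) {
          if (adjustedR2(Y, X[, c(selected, v), drop = FALSE], method) >
              globalAdjR2)
            eligible[v] <- FALSE
        }
      }
      if (!any(eligible)) break
      pick <- remaining[eligible][which.max(added[eligible])]
      selRows[[pick]] <- data.frame(
        variable = pick, added_variance = added[[pick]],
        p_value = p[[pick]], adjusted_p = padj[[pick]],
        n_perm = as.integer(nPerm))
      selected <- c(selected, pick)
    }
  })
  sel <- if (length(selRows)) do.call(rbind, selRows) else
    data.frame(variable = character(0), added_variance = numeric(0),
               p_value = numeric(0), adjusted_p = numeric(0),
               n_perm = integer(0))
  rownames(sel) <- NULL
  uns <- data.frame(variable = setdiff(vars, selected),
                    p_at_entry_test = lastP[setdiff(vars, selected)],
                    row.names = NULL)
  new("ForwardSelectionResult", selected = sel, unselected = uns,
      alpha = alpha, method = method, adjust = adjust,
      seed = as.numeric(seed))
}

#' @describeIn forwardSelect selected variables in order
#' @param object a \linkS4class{ForwardSelectionResult}
#' @export
selectedVariables <- function(object) object@selected$variable

setMethod("show", "ForwardSelectionResult", function(object) {
  cat(sprintf("ForwardSelectionResult (%s, alpha %.3g, %s adjustment)\n",
              object@method, object@alpha, object@adjust))
  if (nrow(object@selected)) print(object@selected, row.names = FALSE)
  else cat("  no variable selected\n")
})
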