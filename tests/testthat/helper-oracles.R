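# Independent brute-force oracles.  Deliberately naive and written against
# the definitions, not the package internals: degenerate matching by full
# expansion + Hamming distance, co-occurrence by per-habitat set
# membership, ordination by dense projection/eigendecomposition with
# explicit solve().

.bfIUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
  H = c("A", "C", "T"), D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T"))

bfExpand <- function(seq) {
  sets <- .bfIUPAC[strsplit(toupper(seq), "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  sort(out)
}

bfHamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# min over expansions of Hamming distance (degenerate-aware mismatch count)
bfMismatch <- function(oligo, window) {
  min(vapply(bfExpand(oligo), bfHamming, numeric(1), b = window))
}

bfRevComp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN",
                            toupper(seq)), "")[[1]]), collapse = "")
}

# exhaustive window/strand enumeration
bfMinMismatch <- function(oligo, target, both = FALSE) {
  L <- nchar(oligo)
  scanOne <- function(o) {
    starts <- 0:(nchar(target) - L)
    mm <- vapply(starts, function(s)
      bfMismatch(o, substr(target, s + 1, s + L)), numeric(1))
    list(mm = min(mm), start = starts[which.min(mm)])
  }
  hit <- scanOne(oligo)
  hit$strand <- "given"
  if (both) {
    hit2 <- scanOne(bfRevComp(oligo))
    if (hit2$mm < hit$mm) { hit2$strand <- "reverse"; hit <- hit2 }
  }
  hit
}

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

randDegenerate <- function(n, nDeg = 2) {
  chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  pos <- sample.int(n, min(nDeg, n))
  chars[pos] <- sample(c("M", "R", "W", "S", "Y", "K"), length(pos),
                       replace = TRUE)
  paste(chars, collapse = "")
}

# dense chi-square residual matrix straight from the definition
bfQbar <- function(Y) {
  tot <- sum(Y)
  E <- outer(rowSums(Y), colSums(Y)) / tot
  (Y - E) / sqrt(E) / sqrt(tot)
}

bfCAEigen <- function(Y) {
  ev <- eigen(crossprod(bfQbar(Y)), symmetric = TRUE)$values
  sort(ev[ev > 1e-12], decreasing = TRUE)
}

# CCA eigenvalues via explicit weighted least squares (solve, not QR)
bfCCAEigen <- function(Y, X) {
  Q <- bfQbar(Y)
  r <- rowSums(Y) / sum(Y)
  Xc <- scale(X, center = colSums(X * r), scale = FALSE)
  sdw <- sqrt(colSums(r * Xc^2))
  Xc <- sweep(Xc, 2, sdw, "/")
  Xw <- Xc * sqrt(r)
  H <- Xw %*% solve(crossprod(Xw)) %*% t(Xw)
  F <- H %*% Q
  ev <- eigen(crossprod(F), symmetric = TRUE)$values
  sort(ev[ev > 1e-12], decreasing = TRUE)
}

# RDA eigenvalues via explicit OLS projection
bfRDAEigen <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  F <- H %*% Yc
  ev <- eigen(crossprod(F) / (nrow(Y) - 1), symmetric = TRUE)$values
  sort(ev[ev > 1e-12], decreasing = TRUE)
}

# per-habitat subset-membership Venn counter
bfVenn <- function(Y, subset) {
  k <- length(subset)
  pats <- apply(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE],
                1, paste, collapse = "")
  counts <- setNames(integer(length(pats)), pats)
  for (h in seq_len(nrow(Y))) {
    p <- paste(Y[h, subset], collapse = "")
    counts[p] <- counts[p] + 1L
  }
  counts
}

# random binary matrix without all-zero rows/columns
randBinaryMatrix <- function(n, m, p = 0.4) {
  repeat {
    Y <- matrix(rbinom(n * m, 1, p), n, m)
    if (all(rowSums(Y) > 0) && all(colSums(Y) > 0)) {
      rownames(Y) <- paste0("h", seq_len(n))
      colnames(Y) <- paste0("g", seq_len(m))
      return(Y)
    }
  }
}

# random non-negative count matrix without zero margins
randCountMatrix <- function(n, m, lambda = 2) {
  repeat {
    Y <- matrix(rpois(n * m, lambda), n, m)
    if (all(rowSums(Y) > 0) && all(colSums(Y) > 0)) return(Y)
  }
}
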