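# Melting-temperature models used to Tm-match a probe panel.  Three models:
# the Wallace 2+4 rule, the GC/salt formula, and nearest-neighbor
# thermodynamics with the unified DNA/DNA dimer parameter set and a
# sodium-dependent entropy correction.  Degenerate oligos are aggregated
# over their concrete expansions (mean/min/max policy).  Internally all
# models run on the bitmask encoding so probe design can score thousands
# of candidate windows cheaply.

#' Melting-temperature model
#'
#' @param kind \code{"wallace"} (2(A+T)+4(G+C)), \code{"gc_salt"}
#'   (81.5 + 16.6 log10 Na + 0.41 \%GC - 600/N) or
#'   \code{"nearest_neighbor"} (unified dimer enthalpies/entropies,
#'   Tm = dH / (dS + R ln(c/4)) - 273.15, with entropy salt correction
#'   0.368 (N-1) ln Na)
#' @param sodiumMolar monovalent cation concentration, mol/L
#' @param oligoMolar total oligo strand concentration, mol/L
#' @param degeneratePolicy aggregation over the expansions of a degenerate
#'   oligo
#' @param degeneracyCap refuse oligos with degeneracy above this
#' @return classed list of model parameters
#' @export
tmModel <- function(kind = c("nearest_neighbor", "wallace", "gc_salt"),
                    sodiumMolar = 0.05, oligoMolar = 2.5e-7,
                    degeneratePolicy = c("mean", "min", "max"),
                    degeneracyCap = 64L) {
  kind <- match.arg(kind)
  degeneratePolicy <- match.arg(degeneratePolicy)
  if (kind != "wallace" && sodiumMolar <= 0) stop("sodiumMolar must be > 0")
  if (kind == "nearest_neighbor" && oligoMolar <= 0)
    stop("oligoMolar must be > 0")
  structure(list(kind = kind, sodiumMolar = sodiumMolar,
                 oligoMolar = oligoMolar,
                 degeneratePolicy = degeneratePolicy,
                 degeneracyCap = as.integer(degeneracyCap)),
            class = "TmModel")
}

# Unified DNA/DNA nearest-neighbor parameters, read once from the vendored
# table (dH kcal/mol, dS cal/mol/K) into 4x4 matrices indexed by base
# index (A=1, C=2, G=3, T=4).
.nnTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "nn_unified_dna.tsv", package = "rlbh",
                          mustWork = TRUE)
      d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
      dH <- setNames(d$dH, d$pair)
      dS <- setNames(d$dS, d$pair)
      dimers <- outer(.BASES, .BASES, paste0)
      cache <<- list(dH16 = matrix(dH[dimers], 4, 4),
                     dS16 = matrix(dS[dimers], 4, 4),
                     initH = c(AT = dH[["init_AT"]], GC = dH[["init_GC"]]),
                     initS = c(AT = dS[["init_AT"]], GC = dS[["init_GC"]]),
                     symS = dS[["init_sym"]])
    }
    cache
  }
})

# Tm of one concrete oligo given as base indices (A=1, C=2, G=3, T=4).
.tmConcreteIdx <- function(bidx, model) {
  n <- length(bidx)
  gc <- sum(bidx == 2L | bidx == 3L)
  switch(model$kind,
    wallace = 2 * (n - gc) + 4 * gc,
    gc_salt = 81.5 + 16.6 * log10(model$sodiumMolar) + 0.41 * (100 * gc / n) -
              600 / n,
    nearest_neighbor = {
      if (n < 8L) stop("nearest_neighbor model needs length >= 8")
      nn <- .nnTable()
      ends <- ifelse(bidx[c(1L, n)] %in% c(2L, 3L), "GC", "AT")
      dH <- sum(nn$dH16[cbind(bidx[-n], bidx[-1L])]) + sum(nn$initH[ends])
      dS <- sum(nn$dS16[cbind(bidx[-n], bidx[-1L])]) + sum(nn$initS[ends])
      selfcomp <- all(rev(5L - bidx) == bidx)
      if (selfcomp) dS <- dS + nn$symS
      dS <- dS + 0.368 * (n - 1) * log(model$sodiumMolar)
      conc <- if (selfcomp) model$oligoMolar else model$oligoMolar / 4
      unname(dH * 1000 / (dS + 1.987 * log(conc)) - 273.15)
    })
}

# Tm of a (possibly degenerate) bitmask vector, aggregated per policy.
.tmFromMask <- function(mask, model) {
  width <- .maskWidth(mask)
  deg <- prod(width)
  if (deg > model$degeneracyCap)
    stop("degeneracy ", deg, " above cap ", model$degeneracyCap)
  baseIdx <- match(mask, c(1L, 2L, 4L, 8L))
  if (deg == 1L) return(.tmConcreteIdx(baseIdx, model))
  degPos <- which(width > 1L)
  options <- lapply(degPos, function(i)
    which(bitwAnd(mask[i], c(1L, 2L, 4L, 8L)) > 0L))
  grid <- as.matrix(expand.grid(options))
  tms <- vapply(seq_len(nrow(grid)), function(k) {
    bidx <- baseIdx
    bidx[degPos] <- grid[k, ]
    .tmConcreteIdx(bidx, model)
  }, numeric(1))
  switch(model$degeneratePolicy,
         mean = mean(tms), min = min(tms), max = max(tms))
}

#' Melting temperature of an oligo
#'
#' @param oligo \linkS4class{DegenerateOligo} or sequence string
#' @param model a \code{\link{tmModel}}
#' @return temperature in degrees Celsius; degenerate oligos are aggregated
#'   over their expansions per the model's policy
#' @examples
#' oligoTm("GGGG", tmModel("wallace"))  # 16
#' @export
oligoTm <- function(oligo, model = tmModel()) {
  if (!inherits(model, "TmModel")) stop("model must be a tmModel()")
  .tmFromMask(.encodeSeq(oligoSequence(.asOligo(oligo))), model)
}

# Batch Tm over candidate windows of one profile mask.
.tmBatchWindows <- function(mask, starts, lens, model) {
  vapply(seq_along(starts), function(i)
    .tmFromMask(mask[(starts[i] + 1L):(starts[i] + lens[i])], model),
    numeric(1))
}

#' Tm spread of a probe panel under one model
#'
#' @param panel \linkS4class{ProbePanel} (or a character vector of
#'   sequences)
#' @param model a \code{\link{tmModel}}
#' @return list with min, max and range (max - min) in degrees Celsius
#' @export
panelTmSpread <- function(panel, model = tmModel()) {
  seqs <- if (is(panel, "ProbePanel")) panel@probes$sequence else panel
  if (!length(seqs)) stop("empty panel")
  tms <- vapply(seqs, oligoTm, numeric(1), model = model)
  list(min = min(tms), max = max(tms), range = max(tms) - min(tms))
}
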