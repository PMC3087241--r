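# Readers/writers for the plain-text interchange formats: FASTA, the
# 2-column strain->groups map, environmental tables, sample pools, panel
# tables and detection matrices.  All tables are UTF-8, tab-separated; '#'
# comment lines are ignored.

#' Read a FASTA file
#'
#' Ids are the first whitespace-delimited token of each header; sequences
#' are upper-cased; record order is preserved.  An empty file yields an
#' empty result; sequence data before the first header is a parse error
#' naming the line.
#'
#' @param path FASTA file path
#' @return named character vector of sequences (names = ids)
#' @importFrom Biostrings readDNAStringSet
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (!length(content)) return(setNames(character(0), character(0)))
  first <- content[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: sequence before header at line ", first)
  x <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  setNames(toupper(as.character(x)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (names become headers)
#' @param path output path
#' @return invisibly, the path
#' @importFrom Biostrings writeXStringSet DNAStringSet
#' @export
writeFasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

.readTsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load a strain collection from FASTA plus a group map
#'
#' The group map is a 2-column tab-separated file with header
#' \code{strain_id<TAB>groups}; the groups column holds comma-separated
#' group labels (empty for ungrouped strains).  Strains absent from the map
#' get an empty group set; map ids missing from the FASTA are an error
#' listing them.
#'
#' @param fasta FASTA file of concrete marker sequences
#' @param groupMap path of the strain->groups map (may be an empty file)
#' @param habitat optional named character of origin habitats per strain
#' @return a \linkS4class{StrainCollection}
#' @export
loadCollection <- function(fasta, groupMap = NULL, habitat = NULL) {
  seqs <- readFasta(fasta)
  if (anyDuplicated(names(seqs)))
    stop("duplicate strain id in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  groups <- setNames(rep(list(character(0)), length(seqs)), names(seqs))
  if (!is.null(groupMap)) {
    map <- tryCatch(.readTsv(groupMap), error = function(e) NULL)
    if (!is.null(map) && nrow(map)) {
      if (anyDuplicated(map[[1L]]))
        stop("duplicate strain id in group map: ",
             paste(unique(map[[1L]][duplicated(map[[1L]])]), collapse = ", "))
      missing <- setdiff(map[[1L]], names(seqs))
      if (length(missing))
        stop("group map references strains missing from FASTA: ",
             paste(missing, collapse = ", "))
      for (i in seq_len(nrow(map))) {
        labs <- trimws(strsplit(as.character(map[[2L]][i]), ",")[[1L]])
        groups[[map[[1L]][i]]] <- labs[nzchar(labs)]
      }
    }
  }
  strainCollection(seqs, groups, habitat)
}

#' Construct a StrainCollection from in-memory data
#'
#' @param seqs named character vector of concrete sequences
#' @param groups named list strain id -> character vector of group labels
#'   (missing strains get empty sets)
#' @param habitat optional named character of origin habitats
#' @return a \linkS4class{StrainCollection}
#' @importFrom Biostrings DNAStringSet
#' @export
strainCollection <- function(seqs, groups = NULL, habitat = NULL) {
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named by strain id")
  full <- setNames(rep(list(character(0)), length(ids)), ids)
  if (!is.null(groups)) {
    unknown <- setdiff(names(groups), ids)
    if (length(unknown))
      stop("groups given for unknown strains: ",
           paste(unknown, collapse = ", "))
    full[names(groups)] <- lapply(groups, as.character)
  }
  hab <- setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(habitat)) hab[names(habitat)] <- habitat
  x <- Biostrings::DNAStringSet(toupper(unname(as.character(seqs))))
  names(x) <- ids
  new("StrainCollection", sequences = x, groups = full, habitat = hab)
}

#' Read an environmental table
#'
#' Tab-separated, first column \code{habitat_id}, remaining columns numeric
#' environmental variables (pH, conductivity, A250, O2, temperature,
#' altitude, ...).
#'
#' @param path TSV path
#' @param missing policy for missing values: keep (default; resolve later
#'   with \code{\link{resolveMissing}}), drop_habitat, or mean_impute
#' @return data.frame with habitat ids as row names
#' @export
readEnvTable <- function(path, missing = c("keep", "drop_habitat", "mean_impute")) {
  missing <- match.arg(missing)
  d <- .readTsv(path)
  rownames(d) <- d[[1L]]
  d <- d[, -1L, drop = FALSE]
  d[] <- lapply(d, as.numeric)
  if (missing != "keep") d <- resolveMissing(d, missing)
  d
}

#' Resolve missing environmental values by an explicit policy
#'
#' @param env data.frame of environmental variables (habitats as rows)
#' @param policy \code{"drop_habitat"} removes rows with any NA;
#'   \code{"mean_impute"} replaces NAs by the column mean
#' @return data.frame without missing values
#' @export
resolveMissing <- function(env, policy = c("drop_habitat", "mean_impute")) {
  policy <- match.arg(policy)
  if (policy == "drop_habitat") {
    env[stats::complete.cases(env), , drop = FALSE]
  } else {
    for (j in seq_along(env)) {
      na <- is.na(env[[j]])
      if (any(na)) env[[j]][na] <- mean(env[[j]], na.rm = TRUE)
    }
    env
  }
}

.writeTsv <- function(d, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    d <- cbind(setNames(data.frame(rownames(d), stringsAsFactors = FALSE),
                        rownames_as), d)
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read sample pools
#'
#' Pools are tidy tables with columns \code{habitat_id}, \code{strain_id},
#' \code{abundance}; abundances are normalized per habitat when read.
#'
#' @param pools data.frame of pools
#' @param path TSV path
#' @return \code{readPools}: the normalized pools data.frame
#' @export
writePools <- function(pools, path) .writeTsv(pools, path)

#' @rdname writePools
#' @export
readPools <- function(path) {
  d <- .readTsv(path)
  d$abundance <- as.numeric(d$abundance)
  normalizePools(d)
}

#' Normalize pool abundances to sum to one per habitat
#'
#' @param pools data.frame with habitat_id, strain_id, abundance
#' @return normalized pools
#' @export
normalizePools <- function(pools) {
  if (any(pools$abundance < 0)) stop("negative abundance")
  tot <- tapply(pools$abundance, pools$habitat_id, sum)
  if (any(tot == 0)) stop("pool with zero total abundance")
  pools$abundance <- pools$abundance / as.numeric(tot[as.character(pools$habitat_id)])
  pools
}

#' Write / read a probe panel table
#'
#' The TSV carries one row per probe (probe, group, sequence, tm,
#' coverage, nontarget_min_mm, degeneracy plus provenance columns); the
#' JSON companion is the structured machine form including the
#' panel-level metadata (strain coverage, uncovered strains, infeasible
#' groups, Tm spread).
#'
#' @param panel a \linkS4class{ProbePanel}
#' @param path TSV path
#' @param jsonPath optional path for the structured JSON form (NULL to
#'   skip)
#' @return \code{readPanel}: a \linkS4class{ProbePanel} rebuilt from the
#'   table (coverage metadata as stored)
#' @export
writePanel <- function(panel, path, jsonPath = NULL) {
  .writeTsv(panel@probes, path)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(probes = panel@probes,
           strain_coverage = panel@strainCoverage,
           uncovered_strains = panel@uncoveredStrains,
           infeasible_groups = panel@infeasibleGroups,
           tm_spread = panel@metadata$tmSpread),
      jsonPath, auto_unbox = TRUE, digits = NA, dataframe = "rows",
      pretty = TRUE)
  }
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path) {
  d <- .readTsv(path)
  new("ProbePanel", probes = d, strainCoverage = NA_real_,
      uncoveredStrains = character(0), infeasibleGroups = character(0),
      metadata = list(source = path))
}

#' Write / read a detection matrix
#'
#' The ordinal TSV stores the signal classes (none/weak/average/
#' very_strong); the binary companion written by \code{writeDetectionMatrix}
#' (suffix \code{.binary.tsv}) stores the 0/1 view under the default
#' binarization rule.
#'
#' @param x a \linkS4class{DetectionMatrix}
#' @param path TSV path for the ordinal matrix
#' @param binaryPath optional path for the 0/1 companion (default: path with
#'   \code{.binary.tsv} appended); NULL to skip
#' @return \code{readDetectionMatrix}: a \linkS4class{DetectionMatrix}
#'   (signals reconstructed as class midpoints are not available, so the
#'   raw signal slot holds the class index)
#' @export
writeDetectionMatrix <- function(x, path, binaryPath = paste0(path, ".binary.tsv")) {
  d <- as.data.frame(x@classes, stringsAsFactors = FALSE)
  .writeTsv(d, path, rownames_as = "habitat_id")
  if (!is.null(binaryPath)) {
    b <- as.data.frame(binarize(x))
    .writeTsv(b, binaryPath, rownames_as = "habitat_id")
  }
  invisible(path)
}

#' @rdname writeDetectionMatrix
#' @export
readDetectionMatrix <- function(path) {
  d <- .readTsv(path)
  rn <- d[[1L]]
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- rn
  if (!all(m %in% .SIGNAL_CLASSES)) stop("unknown signal class in ", path)
  sig <- matrix(match(m, .SIGNAL_CLASSES) - 1L, nrow = nrow(m),
                dimnames = dimnames(m))
  new("DetectionMatrix", signal = sig, classes = m,
      metadata = list(source = path))
}

#' Read a binary habitats x probes matrix from TSV
#'
#' @param path TSV with first column habitat_id and 0/1 probe columns
#' @return integer matrix
#' @export
readBinaryMatrix <- function(path) {
  d <- .readTsv(path)
  rn <- d[[1L]]
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- rn
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("matrix is not binary: ", path)
  m
}

#' Probe and primer sequences of the reference RLBH panel
#'
#' The 13 group-specific ITS probes (F1..F17) and the 4 PCR primers
#' (PnecCf-4, PnecCr-5-BIO, PnecC441f, Poly23Sr) of the freshwater
#' \emph{Polynucleobacter} typing assay, vendored verbatim for regression
#' tests and as ready-made inputs.  Published melting temperatures are
#' carried as reference metadata only.
#'
#' @return data.frame with columns name, type (probe/primer), sequence,
#'   tm_published, biotinylated
#' @export
referenceOligos <- function() {
  path <- system.file("extdata", "reference_oligos.tsv", package = "rlbh",
                      mustWork = TRUE)
  .readTsv(path)
}
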