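#' @importFrom utils read.delim write.table
#' @importFrom Biostrings readDNAStringSet writeXStringSet
NULL

## TSV dialects: UTF-8, tab-separated, "." decimal separator. Trait cells
## that are empty or "ND" denote a non-detection and load as NA; a literal
## 0 is a detected zero.

readTsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", colClasses = "character",
                   check.names = FALSE, na.strings = NULL,
                   fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

## Parse one character column to numeric, treating ""/"ND" as NA and
## reporting the file, 1-based data line (header = line 1) and field on
## failure.
parseNumericColumn <- function(x, path, field, allow_na = TRUE) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  nd <- x == "" | toupper(x) == "ND" | toupper(x) == "NA"
  if (!allow_na && any(nd)) {
    stop(sprintf("%s: line %d: field '%s' is empty", basename(path),
                 which(nd)[1] + 1L, field), call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(x[!nd]))
  if (anyNA(val)) {
    bad <- which(!nd)[which(is.na(val))[1]]
    stop(sprintf("%s: line %d: field '%s' is not numeric: '%s'",
                 basename(path), bad + 1L, field, x[bad]), call. = FALSE)
  }
  out[!nd] <- val
  out
}

checkEnumColumn <- function(x, allowed, path, field) {
  bad <- which(!x %in% allowed)
  if (length(bad)) {
    stop(sprintf("%s: line %d: field '%s' has unknown value '%s' (allowed: %s)",
                 basename(path), bad[1] + 1L, field, x[bad[1]],
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Read a strain collection from its on-disk table dialects
#'
#' Loads `strains.tsv`, `traits.tsv`, `biomass.tsv`, `dilutions.tsv`,
#' `bands.tsv` and (optionally) `alignment.fasta` from `dir` and
#' assembles a validated [StrainCollection-class]. Only `strains.tsv`
#' is mandatory; absent assay files yield empty components.
#'
#' The `source` column may carry a combined provenance label such as
#' `"BS-ORG"` (isolation source, then soil management); it is split into
#' the `source` and `soil` fields. Empty cells or the token `ND` in
#' numeric trait columns load as `NA` (not detected), which is distinct
#' from a stored `0`.
#'
#' @param dir directory holding the table files.
#' @param fasta optional path to the aligned 16S FASTA (defaults to
#'   `alignment.fasta` inside `dir` when present).
#' @return a [StrainCollection-class].
#' @seealso [writeStrainCollection()]
#' @export
readStrainCollection <- function(dir, fasta = NULL) {
  pth <- function(f) file.path(dir, f)

  sf <- readTsv(pth("strains.tsv"),
                c("strain_id", "source", "medium", "genus"))
  src <- trimws(sf$source)
  soil <- if ("soil" %in% names(sf)) trimws(sf$soil) else rep("", nrow(sf))
  combined <- grepl("-", src, fixed = TRUE) & src %in% outer(DZ_SOURCES,
                DZ_SOILS, paste, sep = "-")
  soil[combined] <- sub("^[A-Z]+-", "", src[combined])
  src[combined] <- sub("-[A-Z]+$", "", src[combined])
  strains <- data.frame(
    strain_id = trimws(sf$strain_id),
    source = checkEnumColumn(src, DZ_SOURCES, pth("strains.tsv"), "source"),
    soil = checkEnumColumn(soil, DZ_SOILS, pth("strains.tsv"), "soil"),
    medium = checkEnumColumn(trimws(sf$medium), DZ_MEDIA,
                             pth("strains.tsv"), "medium"),
    genus = trimws(sf$genus), stringsAsFactors = FALSE)

  traits <- emptyTraitFrame()
  if (file.exists(pth("traits.tsv"))) {
    tf <- readTsv(pth("traits.tsv"),
                  c("strain_id", "iaa", "fepo4", "alpo4", "siderophore_index"))
    traits <- data.frame(
      strain_id = trimws(tf$strain_id),
      iaa = parseNumericColumn(tf$iaa, pth("traits.tsv"), "iaa"),
      fepo4 = parseNumericColumn(tf$fepo4, pth("traits.tsv"), "fepo4"),
      alpo4 = parseNumericColumn(tf$alpo4, pth("traits.tsv"), "alpo4"),
      siderophore_index = parseNumericColumn(tf$siderophore_index,
                                             pth("traits.tsv"),
                                             "siderophore_index"),
      stringsAsFactors = FALSE)
  }

  biomass <- emptyBiomassFrame()
  if (file.exists(pth("biomass.tsv"))) {
    bf <- readTsv(pth("biomass.tsv"),
                  c("species", "treatment", "replicate", "rdw", "sdw"))
    biomass <- data.frame(
      species = checkEnumColumn(trimws(bf$species), DZ_SPECIES,
                                pth("biomass.tsv"), "species"),
      treatment = trimws(bf$treatment),
      replicate = as.integer(parseNumericColumn(bf$replicate,
                                                pth("biomass.tsv"),
                                                "replicate", allow_na = FALSE)),
      rdw = parseNumericColumn(bf$rdw, pth("biomass.tsv"), "rdw"),
      sdw = parseNumericColumn(bf$sdw, pth("biomass.tsv"), "sdw"),
      stringsAsFactors = FALSE)
  }

  dilutions <- emptyDilutionFrame()
  if (file.exists(pth("dilutions.tsv"))) {
    df <- readTsv(pth("dilutions.tsv"),
                  c("sample_id", "amount_g", "n_vials", "n_positive"))
    dilutions <- data.frame(
      sample_id = trimws(df$sample_id),
      amount_g = parseNumericColumn(df$amount_g, pth("dilutions.tsv"),
                                    "amount_g", allow_na = FALSE),
      n_vials = as.integer(parseNumericColumn(df$n_vials, pth("dilutions.tsv"),
                                              "n_vials", allow_na = FALSE)),
      n_positive = as.integer(parseNumericColumn(df$n_positive,
                                                 pth("dilutions.tsv"),
                                                 "n_positive",
                                                 allow_na = FALSE)),
      stringsAsFactors = FALSE)
  }

  bands <- list()
  if (file.exists(pth("bands.tsv"))) {
    kf <- readTsv(pth("bands.tsv"), c("strain_id", "bands"))
    bands <- lapply(seq_len(nrow(kf)), function(i) {
      cell <- trimws(kf$bands[i])
      if (!nzchar(cell)) return(numeric())
      v <- suppressWarnings(as.numeric(strsplit(cell, ",", fixed = TRUE)[[1]]))
      if (anyNA(v)) {
        stop(sprintf("bands.tsv: line %d: field 'bands' is not a comma-separated numeric list",
                     i + 1L), call. = FALSE)
      }
      sort(v)
    })
    names(bands) <- trimws(kf$strain_id)
  }

  if (is.null(fasta)) {
    fasta <- pth("alignment.fasta")
    if (!file.exists(fasta)) fasta <- NA
  }
  alignment <- if (is.character(fasta) && !is.na(fasta)) {
    readDNAStringSet(fasta)
  } else {
    DNAStringSet()
  }

  StrainCollection(strains = strains, traits = traits, biomass = biomass,
                   dilutions = dilutions, bands = bands,
                   alignment = alignment)
}

fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.10g", v)
  }, character(1))
  out
}

#' Write a strain collection to its on-disk table dialects
#'
#' Emits `strains.tsv`, `traits.tsv`, `biomass.tsv`, `dilutions.tsv`,
#' `bands.tsv` and, when the collection carries aligned sequences,
#' `alignment.fasta` under `dir`. Numeric values are written with 10
#' significant digits so that [readStrainCollection()] round-trips the
#' collection; non-detections are written as empty cells.
#'
#' @param x a [StrainCollection-class].
#' @param dir output directory (created if absent).
#' @return invisibly, `dir`.
#' @seealso [readStrainCollection()]
#' @export
writeStrainCollection <- function(x, dir) {
  stopifnot(is(x, "StrainCollection"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  w <- function(df, f) {
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  w(x@strains, "strains.tsv")

  tr <- x@traits
  for (v in c("iaa", "fepo4", "alpo4", "siderophore_index")) tr[[v]] <- fmtNum(tr[[v]])
  w(tr, "traits.tsv")

  bm <- x@biomass
  for (v in c("rdw", "sdw")) bm[[v]] <- fmtNum(bm[[v]])
  w(bm, "biomass.tsv")

  dl <- x@dilutions
  dl$amount_g <- fmtNum(dl$amount_g)
  w(dl, "dilutions.tsv")

  bd <- data.frame(
    strain_id = names(x@bands),
    bands = vapply(x@bands, function(b) paste(sprintf("%.10g", b),
                                              collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  if (!nrow(bd)) bd <- data.frame(strain_id = character(), bands = character())
  w(bd, "bands.tsv")

  if (length(x@alignment)) {
    writeXStringSet(x@alignment, file.path(dir, "alignment.fasta"))
  }
  invisible(dir)
}
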