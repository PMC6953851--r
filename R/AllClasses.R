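#' @import methods
#' @importFrom Biostrings DNAStringSet width alphabetFrequency
NULL

## Controlled vocabularies shared by readers, validators and the simulator.
## Sources: BS = bulk soil, TR = tomato unwashed roots, LR = lulo unwashed
## roots. Soils: SF = secondary forest, CH = conventional horticulture,
## ORG = organic horticulture. Media are the five semisolid N-free media
## used for diazotroph/N-scavenger isolation.
DZ_SOURCES <- c("BS", "TR", "LR")
DZ_SOILS <- c("SF", "CH", "ORG")
DZ_MEDIA <- c("JMV", "NFb", "JNFb", "LGI", "LGI-P")
DZ_SPECIES <- c("tomato", "lulo")
DZ_CONTROL <- "CONTROL"

#' Normalize a strain identifier for comparison
#'
#' Strain labels are compared after stripping leading zeros from their
#' numeric prefix, so that `"04T"` and `"4T"` (or `"019S"` and `"19S"`)
#' refer to the same strain. The stored label is never rewritten; only
#' comparisons and joins use the normalized form. Identifiers without a
#' leading digit (e.g. `"CONTROL"`) are returned unchanged.
#'
#' @param x character vector of strain identifiers.
#' @return character vector of normalized identifiers.
#' @examples
#' normalizeStrainId(c("04T", "4T", "019S", "CONTROL"))
#' @export
normalizeStrainId <- function(x) {
  x <- as.character(x)
  sub("^0+(?=[0-9])", "", x, perl = TRUE)
}

emptyStrainFrame <- function() {
  data.frame(strain_id = character(), source = character(),
             soil = character(), medium = character(),
             genus = character(), stringsAsFactors = FALSE)
}

emptyTraitFrame <- function() {
  data.frame(strain_id = character(), iaa = numeric(), fepo4 = numeric(),
             alpo4 = numeric(), siderophore_index = numeric(),
             stringsAsFactors = FALSE)
}

emptyBiomassFrame <- function() {
  data.frame(species = character(), treatment = character(),
             replicate = integer(), rdw = numeric(), sdw = numeric(),
             stringsAsFactors = FALSE)
}

emptyDilutionFrame <- function() {
  data.frame(sample_id = character(), amount_g = numeric(),
             n_vials = integer(), n_positive = integer(),
             stringsAsFactors = FALSE)
}

#' StrainCollection: the central container of a screening study
#'
#' An S4 class holding every data stream of a culturable-microbiome strain
#' screen: strain provenance records, in vitro trait measurements,
#' greenhouse biomass observations, serial-dilution (MPN) outcomes,
#' rep-PCR band profiles and an optional aligned set of 16S rRNA
#' sequences. All analysis stages of the package consume this container
#' (or the plain vectors/data frames extracted from it by its accessors).
#'
#' Trait values use `NA` for "not detected": a strain that was assayed but
#' produced no measurable signal. A stored numeric `0` is a detected zero;
#' both score 0 on the bonitur scale but they are distinct in storage.
#'
#' @slot strains data.frame with columns `strain_id`, `source` (BS/TR/LR),
#'   `soil` (SF/CH/ORG), `medium` (JMV/NFb/JNFb/LGI/LGI-P), `genus`.
#' @slot traits data.frame with columns `strain_id`, `iaa`
#'   (ug IAA per mg protein), `fepo4` and `alpo4` (solubilized P, mg per
#'   unit volume or mass as assayed), `siderophore_index` (halo/colony
#'   diameter ratio, >= 1 when detected). `NA` means not detected.
#' @slot biomass data.frame with columns `species` (tomato/lulo),
#'   `treatment` (a strain id or `"CONTROL"`), `replicate`, `rdw`, `sdw`
#'   (g per plant).
#' @slot dilutions data.frame with columns `sample_id`, `amount_g`
#'   (grams of original material per inoculated vial), `n_vials`,
#'   `n_positive`; amounts strictly decreasing within a sample.
#' @slot bands named list (by strain id) of ascending fragment sizes (bp).
#' @slot alignment [Biostrings::DNAStringSet] of equal-width aligned 16S
#'   sequences (possibly empty), alphabet restricted to A, C, G, T, -, N.
#'
#' @seealso [StrainCollection()] for construction,
#'   [readStrainCollection()] / [writeStrainCollection()] for on-disk
#'   form, [simulateCollection()] for synthetic collections.
#' @export
setClass("StrainCollection",
         slots = c(strains = "data.frame",
                   traits = "data.frame",
                   biomass = "data.frame",
                   dilutions = "data.frame",
                   bands = "list",
                   alignment = "DNAStringSet"))

validStrainCollection <- function(object) {
  msg <- character()
  st <- object@strains
  need <- c("strain_id", "source", "soil", "medium", "genus")
  if (!all(need %in% names(st))) {
    return(paste("strains is missing columns:",
                 paste(setdiff(need, names(st)), collapse = ", ")))
  }
  if (anyDuplicated(st$strain_id)) {
    msg <- c(msg, "duplicated strain_id in strains table")
  }
  bad <- setdiff(unique(st$source), DZ_SOURCES)
  if (length(bad)) {
    msg <- c(msg, paste("unknown source value(s):", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(st$soil), DZ_SOILS)
  if (length(bad)) {
    msg <- c(msg, paste("unknown soil value(s):", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(st$medium), DZ_MEDIA)
  if (length(bad)) {
    msg <- c(msg, paste("unknown medium value(s):", paste(bad, collapse = ", ")))
  }

  tr <- object@traits
  if (nrow(tr)) {
    num <- c("iaa", "fepo4", "alpo4", "siderophore_index")
    for (v in num) {
      if (any(tr[[v]] < 0, na.rm = TRUE)) {
        msg <- c(msg, paste("negative", v, "trait value"))
      }
    }
    si <- tr$siderophore_index
    if (any(si[!is.na(si)] > 0 & si[!is.na(si)] < 1)) {
      msg <- c(msg, "detected siderophore_index must be >= 1 (halo >= colony)")
    }
  }

  bm <- object@biomass
  if (nrow(bm)) {
    bad <- setdiff(unique(bm$species), DZ_SPECIES)
    if (length(bad)) {
      msg <- c(msg, paste("unknown species value(s):", paste(bad, collapse = ", ")))
    }
    if (any(bm$rdw < 0, na.rm = TRUE) || any(bm$sdw < 0, na.rm = TRUE)) {
      msg <- c(msg, "negative dry weight in biomass table")
    }
    for (sp in unique(bm$species)) {
      if (!DZ_CONTROL %in% bm$treatment[bm$species == sp]) {
        msg <- c(msg, paste0("biomass table for species '", sp,
                             "' lacks a CONTROL treatment"))
      }
    }
  }

  dl <- object@dilutions
  if (nrow(dl)) {
    if (any(dl$amount_g <= 0)) msg <- c(msg, "non-positive dilution amount")
    if (any(dl$n_vials < 1)) msg <- c(msg, "n_vials must be >= 1")
    if (any(dl$n_positive < 0 | dl$n_positive > dl$n_vials)) {
      msg <- c(msg, "n_positive must lie in [0, n_vials]")
    }
    for (sid in unique(dl$sample_id)) {
      a <- dl$amount_g[dl$sample_id == sid]
      if (any(diff(a) >= 0)) {
        msg <- c(msg, paste0("dilution amounts for sample '", sid,
                             "' are not strictly decreasing"))
      }
    }
  }

  bp <- object@bands
  if (length(bp)) {
    if (is.null(names(bp)) || any(!nzchar(names(bp)))) {
      msg <- c(msg, "band profiles must be named by strain_id")
    }
    for (i in seq_along(bp)) {
      b <- bp[[i]]
      if (length(b)) {
        if (any(b <= 0)) msg <- c(msg, "band sizes must be positive")
        if (is.unsorted(b)) msg <- c(msg, "band profiles must be sorted ascending")
        if (anyDuplicated(round(b))) {
          msg <- c(msg, paste0("duplicate band (after 1 bp rounding) in profile '",
                               names(bp)[i], "'"))
        }
      }
    }
  }

  aln <- object@alignment
  if (length(aln)) {
    if (length(unique(width(aln))) != 1L) {
      msg <- c(msg, "aligned sequences must have equal length")
    }
    af <- alphabetFrequency(aln)
    allowed <- c("A", "C", "G", "T", "-", "N")
    extra <- rowSums(af) - rowSums(af[, allowed, drop = FALSE])
    if (any(extra > 0)) {
      msg <- c(msg, "alignment alphabet restricted to A, C, G, T, -, N")
    }
  }

  if (length(msg)) msg else TRUE
}

setValidity("StrainCollection", validStrainCollection)

#' Construct a StrainCollection
#'
#' Assembles the container from its component tables, validates all
#' structural invariants, and warns about assay rows referring to strain
#' ids absent from the strain table (comparison after leading-zero
#' normalization, see [normalizeStrainId()]).
#'
#' @param strains,traits,biomass,dilutions data.frames as documented in
#'   [StrainCollection-class]; missing pieces default to empty tables.
#' @param bands named list of ascending band sizes (bp) per strain.
#' @param alignment a [Biostrings::DNAStringSet] of aligned 16S sequences,
#'   or anything coercible to one (e.g. a named character vector).
#' @return a validated [StrainCollection-class] object.
#' @examples
#' sc <- StrainCollection(
#'   strains = data.frame(strain_id = "19S", source = "BS", soil = "ORG",
#'                        medium = "JMV", genus = "Enterobacter"),
#'   traits = data.frame(strain_id = "19S", iaa = 120, fepo4 = 12.1,
#'                       alpo4 = 4.0, siderophore_index = NA))
#' sc
#' @export
StrainCollection <- function(strains = emptyStrainFrame(),
                             traits = emptyTraitFrame(),
                             biomass = emptyBiomassFrame(),
                             dilutions = emptyDilutionFrame(),
                             bands = list(),
                             alignment = DNAStringSet()) {
  strains <- as.data.frame(strains, stringsAsFactors = FALSE)
  traits <- as.data.frame(traits, stringsAsFactors = FALSE)
  biomass <- as.data.frame(biomass, stringsAsFactors = FALSE)
  dilutions <- as.data.frame(dilutions, stringsAsFactors = FALSE)
  if (!is(alignment, "DNAStringSet")) alignment <- DNAStringSet(alignment)
  rownames(strains) <- rownames(traits) <- NULL
  rownames(biomass) <- rownames(dilutions) <- NULL

  obj <- new("StrainCollection", strains = strains, traits = traits,
             biomass = biomass, dilutions = dilutions, bands = bands,
             alignment = alignment)

  known <- normalizeStrainId(strains$strain_id)
  checkRefs <- function(ids, what) {
    ids <- setdiff(unique(normalizeStrainId(ids)), c(known, DZ_CONTROL))
    if (length(ids)) {
      warning(sprintf("%s refer to strain id(s) absent from the strain table: %s",
                      what, paste(ids, collapse = ", ")), call. = FALSE)
    }
  }
  if (nrow(traits)) checkRefs(traits$strain_id, "trait measurements")
  if (nrow(biomass)) checkRefs(biomass$treatment, "biomass observations")
  if (length(bands)) checkRefs(names(bands), "band profiles")
  if (length(alignment)) checkRefs(names(alignment), "aligned sequences")
  obj
}

#' @describeIn StrainCollection-class number of strains in the collection
#' @param x,object a `StrainCollection`.
#' @export
setMethod("length", "StrainCollection", function(x) nrow(x@strains))

setMethod("show", "StrainCollection", function(object) {
  cat("StrainCollection with", nrow(object@strains), "strains\n")
  if (nrow(object@strains)) {
    gen <- sort(table(object@strains$genus), decreasing = TRUE)
    cat("  genera:", paste(sprintf("%s (%d)", names(gen), gen), collapse = ", "),
        "\n")
  }
  cat("  traits:", nrow(object@traits), "measurement rows\n")
  cat("  biomass:", nrow(object@biomass), "observations on",
      length(unique(object@biomass$species)), "species\n")
  cat("  dilutions:", length(unique(object@dilutions$sample_id)),
      "MPN dilution series\n")
  cat("  band profiles:", length(object@bands), "| aligned 16S:",
      length(object@alignment), "\n")
})
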