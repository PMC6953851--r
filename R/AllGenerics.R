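#' Accessors for StrainCollection components
#'
#' Extract the component tables of a [StrainCollection-class] without
#' touching slots directly.
#'
#' @param x a [StrainCollection-class].
#' @return `strainInfo`: the strain provenance data.frame; `traitValues`:
#'   the trait measurement data.frame (`NA` = not detected);
#'   `biomassData`: the greenhouse observation data.frame;
#'   `dilutionData`: the serial-dilution outcome data.frame;
#'   `bandProfiles`: the named list of band-size vectors;
#'   `alignment16S`: the [Biostrings::DNAStringSet] alignment.
#' @name StrainCollection-accessors
NULL

#' @rdname StrainCollection-accessors
#' @export
setGeneric("strainInfo", function(x) standardGeneric("strainInfo"))

#' @rdname StrainCollection-accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))

#' @rdname StrainCollection-accessors
#' @export
setGeneric("biomassData", function(x) standardGeneric("biomassData"))

#' @rdname StrainCollection-accessors
#' @export
setGeneric("dilutionData", function(x) standardGeneric("dilutionData"))

#' @rdname StrainCollection-accessors
#' @export
setGeneric("bandProfiles", function(x) standardGeneric("bandProfiles"))

#' @rdname StrainCollection-accessors
#' @export
setGeneric("alignment16S", function(x) standardGeneric("alignment16S"))

#' @rdname StrainCollection-accessors
#' @export
setMethod("strainInfo", "StrainCollection", function(x) x@strains)

#' @rdname StrainCollection-accessors
#' @export
setMethod("traitValues", "StrainCollection", function(x) x@traits)

#' @rdname StrainCollection-accessors
#' @export
setMethod("biomassData", "StrainCollection", function(x) x@biomass)

#' @rdname StrainCollection-accessors
#' @export
setMethod("dilutionData", "StrainCollection", function(x) x@dilutions)

#' @rdname StrainCollection-accessors
#' @export
setMethod("bandProfiles", "StrainCollection", function(x) x@bands)

#' @rdname StrainCollection-accessors
#' @export
setMethod("alignment16S", "StrainCollection", function(x) x@alignment)
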