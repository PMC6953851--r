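#' Reference summary tables of the 101-strain screening survey
#'
#' Small plain-text tables distributed with the package, summarizing a
#' screening survey of 101 diazotrophic/N-scavenging strains isolated
#' from three soil managements (SF, CH, ORG) and three isolation sources
#' (bulk soil, tomato and lulo unwashed roots) on five semisolid N-free
#' media. They serve as worked-example inputs for the aggregation and
#' scoring stages:
#'
#' * `referenceMpnTable()`: per-sample, per-medium isolate counts (`n`)
#'   and display MPN values (units of 1e4 cells/g), with the published
#'   per-sample totals in `printed_total`.
#' * `referenceBoniturScores()`: the 24 strains with bonitur total >= 10
#'   — the eight component scores per strain plus the published total
#'   and dense rank.
#' * `referenceGenusCounts()`: genus-level strain counts with their
#'   proteobacterial class.
#'
#' @return a data.frame (see above).
#' @examples
#' summarizeMPN(referenceMpnTable())$soil_means
#' @name reference-data
NULL

refTsv <- function(f) {
  read.delim(system.file("extdata", f, package = "diazoScreen",
                         mustWork = TRUE),
             sep = "\t", check.names = FALSE, stringsAsFactors = FALSE,
             fileEncoding = "UTF-8")
}

#' @rdname reference-data
#' @export
referenceMpnTable <- function() refTsv("reference_mpn.tsv")

#' @rdname reference-data
#' @export
referenceBoniturScores <- function() {
  df <- refTsv("reference_bonitur.tsv")
  df$strain_id <- as.character(df$strain_id)
  df
}

#' @rdname reference-data
#' @export
referenceGenusCounts <- function() refTsv("reference_genus.tsv")
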