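#' @importFrom stats setNames
NULL

## Proteobacterial class of each genus observed in diazotroph/N-scavenger
## screens; used for the class-level rollup of genusDistribution().
DZ_GENUS_CLASS <- c(
  Rhizobium = "Alphaproteobacteria", Caulobacter = "Alphaproteobacteria",
  Novosphingobium = "Alphaproteobacteria",
  Burkholderia = "Betaproteobacteria", Cupriavidus = "Betaproteobacteria",
  Variovorax = "Betaproteobacteria", Pelomonas = "Betaproteobacteria",
  Pseudomonas = "Gammaproteobacteria", Enterobacter = "Gammaproteobacteria",
  Stenotrophomonas = "Gammaproteobacteria",
  Xanthomonas = "Gammaproteobacteria")

DZ_TRAITS <- c("iaa", "fepo4", "alpo4", "siderophore_index")

#' Summarize in vitro trait measurements over a collection
#'
#' For each of the four plant growth-promoting traits (IAA synthesis,
#' FePO4 and AlPO4 solubilization, siderophore production): the count of
#' positive strains, the mean over positive strains only (the "mean
#' trait value" that anchors bonitur scoring), and the observed range.
#' Also cross-tabulates positive counts by isolation source and by
#' genus, and counts strain co-occurrence over every subset of the four
#' traits.
#'
#' A strain is positive for a trait when the measurement is detected
#' (non-`NA`) and greater than zero.
#'
#' @param traits trait data.frame ([traitValues()]).
#' @param strains strain data.frame ([strainInfo()]); optional, enables
#'   the per-source and per-genus cross-tabulations.
#' @return list with `per_trait` (data.frame: trait, n_positive, mean,
#'   min, max), `n_strains`, `n_at_least_one`, `n_multi`,
#'   `co_occurrence` (named counts over trait subsets, names like
#'   `"iaa+fepo4"`, exact-subset counts), and, when `strains` is given,
#'   `by_source` and `by_genus` positive-count tables.
#' @export
traitSummary <- function(traits, strains = NULL) {
  pos <- vapply(DZ_TRAITS, function(v) {
    !is.na(traits[[v]]) & traits[[v]] > 0
  }, logical(nrow(traits)))
  pos <- matrix(pos, nrow = nrow(traits), dimnames = list(NULL, DZ_TRAITS))

  per_trait <- do.call(rbind, lapply(DZ_TRAITS, function(v) {
    p <- traits[[v]][pos[, v]]
    data.frame(trait = v, n_positive = length(p),
               mean = if (length(p)) mean(p) else NA_real_,
               min = if (length(p)) min(p) else NA_real_,
               max = if (length(p)) max(p) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  subset_key <- apply(pos, 1, function(z) paste(DZ_TRAITS[z], collapse = "+"))
  subset_key[subset_key == ""] <- "(none)"
  co <- table(subset_key)

  out <- list(per_trait = per_trait,
              n_strains = nrow(traits),
              n_at_least_one = sum(rowSums(pos) >= 1),
              n_multi = sum(rowSums(pos) >= 2),
              co_occurrence = setNames(as.integer(co), names(co)))

  if (!is.null(strains)) {
    idx <- match(normalizeStrainId(traits$strain_id),
                 normalizeStrainId(strains$strain_id))
    src <- strains$source[idx]
    gen <- strains$genus[idx]
    out$by_source <- sapply(DZ_TRAITS, function(v) {
      tapply(pos[, v], factor(src, levels = DZ_SOURCES), sum, default = 0L)
    })
    out$by_genus <- sapply(DZ_TRAITS, function(v) {
      tapply(pos[, v], gen, sum, default = 0L)
    })
  }
  out
}

#' Bonitur score for one in vitro trait value
#'
#' Converts a trait measurement into a 0-3 bin relative to the mean
#' trait value over positive strains. In the default `"band"` mode the
#' bin bounds are `0.65 * mean` and `1.35 * mean` (a symmetric 35% band
#' around the mean; with a mean of 3.85 this reproduces published
#' 1-decimal cutoffs 2.5 and 5.2). The `"literal"` mode places them at
#' `0.35 * mean` and `0.70 * mean` instead. Not-detected (`NA`) and
#' detected-zero values score 0; a value on a bound is assigned the
#' higher bin (lower bound -> 2, upper bound -> 3).
#'
#' @param value numeric trait value(s); `NA` = not detected.
#' @param mean_trait positive-strain mean of the trait (> 0).
#' @param mode `"band"` (default) or `"literal"`.
#' @return integer score(s) in `{0, 1, 2, 3}`.
#' @examples
#' traitScore(c(NA, 3.0, 17.05), mean_trait = 3.85) # 0 2 3
#' @export
traitScore <- function(value, mean_trait, mode = c("band", "literal")) {
  mode <- match.arg(mode)
  if (mean_trait <= 0) stop("mean_trait must be positive")
  if (any(value < 0, na.rm = TRUE)) stop("trait values must be >= 0")
  bounds <- if (mode == "band") c(0.65, 1.35) else c(0.35, 0.70)
  lo <- bounds[1] * mean_trait
  hi <- bounds[2] * mean_trait
  score <- ifelse(is.na(value) | value == 0, 0L,
                  1L + (value >= lo) + (value >= hi))
  as.integer(score)
}

#' Bonitur score for a biometric response, relative to the control
#'
#' Scores a treatment 0/1/2 according to the position of its Scott-Knott
#' cluster relative to the uninoculated control's cluster: 0 when the
#' strain's cluster ranks below the control's (significantly lower
#' biomass), 1 when they share a cluster, and 2 when the strain's
#' cluster ranks above.
#'
#' @param treatment treatment id(s) to score.
#' @param grouping a `dzMeansGrouping` from [scottKnott()].
#' @param control the control treatment label (default `"CONTROL"`).
#' @return integer score(s) in `{0, 1, 2}`.
#' @seealso [cutoffScore()] for the fixed-cutoff replay mode.
#' @export
biometricScore <- function(treatment, grouping, control = DZ_CONTROL) {
  stopifnot(inherits(grouping, "dzMeansGrouping"))
  key <- normalizeStrainId(grouping$treatment)
  gc <- grouping$group[match(normalizeStrainId(control), key)]
  if (is.na(gc)) stop("control treatment absent from grouping")
  gs <- grouping$group[match(normalizeStrainId(treatment), key)]
  if (anyNA(gs)) {
    stop("treatment(s) absent from grouping: ",
         paste(treatment[is.na(gs)], collapse = ", "))
  }
  ## group 1 holds the highest means, so a smaller number ranks above
  as.integer(ifelse(gs < gc, 2L, ifelse(gs == gc, 1L, 0L)))
}

#' Fixed-cutoff 0/1/2 score for a biometric mean
#'
#' Replays published per-response cutoff bounds: 0 when the mean is
#' below `lower`, 1 between the bounds, 2 at or above `upper`; boundary
#' values take the higher bin.
#'
#' @param value biometric mean(s), g per plant.
#' @param lower,upper the two cutoff bounds (`lower < upper`).
#' @return integer score(s) in `{0, 1, 2}`; `NA` propagates.
#' @examples
#' cutoffScore(c(0.30, 0.70), 0.23, 0.27) # 2 2
#' @export
cutoffScore <- function(value, lower, upper) {
  stopifnot(lower < upper)
  as.integer((value >= lower) + (value >= upper))
}

#' Dense ranks for bonitur totals
#'
#' Equal totals share a rank; the next distinct total receives the next
#' consecutive integer (1 = highest total).
#'
#' @param totals numeric vector of bonitur totals.
#' @return integer vector of dense ranks.
#' @examples
#' rankStrains(c(14, 12, 12, 11)) # 1 2 2 3
#' @export
rankStrains <- function(totals) {
  if (!length(totals)) return(integer())
  match(totals, sort(unique(totals), decreasing = TRUE))
}

#' Assemble bonitur results from the eight component scores
#'
#' Validates ranges (trait scores 0-3, biometric scores 0-2), sums the
#' components into the 0-20 total, assigns dense ranks and flags
#' biotechnological potential (total >= 10). Rows are reordered by rank,
#' then strain id (display order only: tied totals share their rank).
#'
#' @param scores data.frame with a `strain_id` column, trait columns
#'   `iaa`, `fepo4`, `alpo4`, `siderophore`, and biometric columns
#'   `tomato_rdw`, `tomato_sdw`, `lulo_rdw`, `lulo_sdw`.
#' @return data.frame with the components plus `total`, `rank`,
#'   `biotech_potential`.
#' @export
boniturFromScores <- function(scores) {
  trait_cols <- c("iaa", "fepo4", "alpo4", "siderophore")
  bio_cols <- c("tomato_rdw", "tomato_sdw", "lulo_rdw", "lulo_sdw")
  stopifnot(all(c("strain_id", trait_cols, bio_cols) %in% names(scores)))
  for (v in trait_cols) {
    if (any(!scores[[v]] %in% 0:3)) stop("trait score out of range in ", v)
  }
  for (v in bio_cols) {
    if (any(!scores[[v]] %in% 0:2)) stop("biometric score out of range in ", v)
  }
  out <- scores
  out$total <- rowSums(out[, c(trait_cols, bio_cols)])
  out$rank <- rankStrains(out$total)
  out$biotech_potential <- out$total >= 10
  out <- out[order(out$rank, out$strain_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end bonitur scoring of a strain collection
#'
#' Runs the complete prioritization chain: computes each trait's mean
#' over positive strains, bins every strain's trait values
#' ([traitScore()]), fits one-way ANOVA and Scott-Knott groupings per
#' species and response ([oneWayAnova()], [scottKnott()]), scores the
#' four biometric components relative to the uninoculated control
#' ([biometricScore()]), and assembles totals, dense ranks and the
#' biotechnological-potential flag (total >= 10, of a 20-point maximum:
#' four traits x 3 + four biometric components x 2).
#'
#' Strains absent from the greenhouse trial receive `NA` biometric
#' scores and no total.
#'
#' @param collection a [StrainCollection-class] with traits and biomass.
#' @param mode trait binning mode, see [traitScore()].
#' @param alpha Scott-Knott significance level.
#' @param control control treatment label in the biomass table.
#' @return data.frame as in [boniturFromScores()], plus a
#'   `"trait_means"` attribute (the positive-strain means used) and a
#'   `"groupings"` attribute (the four `dzMeansGrouping` objects).
#' @export
boniturTable <- function(collection, mode = c("band", "literal"),
                         alpha = 0.05, control = DZ_CONTROL) {
  mode <- match.arg(mode)
  stopifnot(is(collection, "StrainCollection"))
  traits <- traitValues(collection)
  biomass <- biomassData(collection)
  if (!nrow(traits)) stop("collection has no trait measurements")
  if (!nrow(biomass)) stop("collection has no biomass observations")

  ts <- traitSummary(traits)
  tmeans <- setNames(ts$per_trait$mean, ts$per_trait$trait)

  scores <- data.frame(strain_id = traits$strain_id, stringsAsFactors = FALSE)
  col_of <- c(iaa = "iaa", fepo4 = "fepo4", alpo4 = "alpo4",
              siderophore = "siderophore_index")
  for (sc in names(col_of)) {
    v <- traits[[col_of[[sc]]]]
    scores[[sc]] <- if (is.na(tmeans[[col_of[[sc]]]])) {
      rep(0L, length(v)) # no positive strain anywhere: trait cannot score
    } else {
      traitScore(v, tmeans[[col_of[[sc]]]], mode)
    }
  }

  groupings <- list()
  for (sp in intersect(DZ_SPECIES, unique(biomass$species))) {
    for (resp in c("rdw", "sdw")) {
      g <- scottKnott(oneWayAnova(biomass, sp, resp), alpha)
      groupings[[paste(sp, resp, sep = "_")]] <- g
      key <- normalizeStrainId(g$treatment)
      present <- normalizeStrainId(scores$strain_id) %in% key
      col <- rep(NA_integer_, nrow(scores))
      col[present] <- biometricScore(scores$strain_id[present], g, control)
      scores[[paste(sp, resp, sep = "_")]] <- col
    }
  }
  for (v in c("tomato_rdw", "tomato_sdw", "lulo_rdw", "lulo_sdw")) {
    if (is.null(scores[[v]])) scores[[v]] <- NA_integer_
  }

  complete <- !is.na(scores$tomato_rdw + scores$tomato_sdw +
                       scores$lulo_rdw + scores$lulo_sdw)
  out <- scores
  out$total <- NA_real_
  out$total[complete] <- rowSums(out[complete, c("iaa", "fepo4", "alpo4",
                                                 "siderophore", "tomato_rdw",
                                                 "tomato_sdw", "lulo_rdw",
                                                 "lulo_sdw")])
  out$rank <- NA_integer_
  out$rank[complete] <- rankStrains(out$total[complete])
  out$biotech_potential <- !is.na(out$total) & out$total >= 10
  out <- out[order(out$rank, out$strain_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_means") <- tmeans
  attr(out, "groupings") <- groupings
  out
}

#' Genus distribution of a strain collection
#'
#' Counts and 1-decimal percentages per genus, plus the rollup to
#' proteobacterial classes.
#'
#' @param strains strain data.frame ([strainInfo()]).
#' @return list with `genera` (data.frame: genus, n, pct, class) ordered
#'   by decreasing count, and `classes` (data.frame: class, n, pct).
#' @examples
#' genusDistribution(data.frame(strain_id = 1:4, source = "BS",
#'   soil = "SF", medium = "JMV",
#'   genus = c("Rhizobium", "Rhizobium", "Pseudomonas", "Burkholderia")))
#' @export
genusDistribution <- function(strains) {
  n <- nrow(strains)
  if (!n) {
    return(list(genera = data.frame(genus = character(), n = integer(),
                                    pct = numeric(), class = character()),
                classes = data.frame(class = character(), n = integer(),
                                     pct = numeric())))
  }
  cnt <- sort(table(strains$genus), decreasing = TRUE)
  genera <- data.frame(genus = names(cnt), n = as.integer(cnt),
                       pct = round(100 * as.integer(cnt) / n, 1),
                       class = unname(ifelse(names(cnt) %in% names(DZ_GENUS_CLASS),
                                             DZ_GENUS_CLASS[names(cnt)],
                                             "unclassified")),
                       stringsAsFactors = FALSE)
  rownames(genera) <- NULL
  ccnt <- sort(tapply(genera$n, genera$class, sum), decreasing = TRUE)
  classes <- data.frame(class = names(ccnt), n = as.integer(ccnt),
                        pct = round(100 * as.integer(ccnt) / n, 1),
                        stringsAsFactors = FALSE)
  rownames(classes) <- NULL
  list(genera = genera, classes = classes)
}

#' Full screening report for a collection
#'
#' Convenience wrapper running every stage present in the collection:
#' trait summary, genus distribution, MPN estimates (when dilution
#' series are present), fingerprint profile counting (when band
#' profiles are present) and the bonitur ranking (when both traits and
#' biomass are present).
#'
#' @param collection a [StrainCollection-class].
#' @param tol,cutoff,clone_threshold fingerprint parameters (see
#'   [bandSimilarityMatrix()], [cutClusters()], [countProfiles()]).
#' @param mode,alpha bonitur parameters (see [boniturTable()]).
#' @return list with any of `traits`, `genus`, `mpn`, `fingerprint`
#'   (list: `groups`, `n_groups`, `profiles`), `bonitur`.
#' @export
screenStrains <- function(collection, tol = 0.02, cutoff = 0.70,
                          clone_threshold = 0.95,
                          mode = c("band", "literal"), alpha = 0.05) {
  mode <- match.arg(mode)
  out <- list()
  st <- strainInfo(collection)
  out$genus <- genusDistribution(st)
  if (nrow(traitValues(collection))) {
    out$traits <- traitSummary(traitValues(collection), st)
  }
  if (nrow(dilutionData(collection))) {
    out$mpn <- estimateMPNAll(dilutionData(collection))
  }
  bands <- bandProfiles(collection)
  if (length(bands) >= 2) {
    sim <- bandSimilarityMatrix(bands, tol)
    groups <- cutClusters(upgmaDendrogram(sim), cutoff)
    out$fingerprint <- list(groups = groups,
                            n_groups = length(unique(groups)),
                            profiles = countProfiles(sim, clone_threshold))
  }
  if (nrow(traitValues(collection)) && nrow(biomassData(collection))) {
    out$bonitur <- boniturTable(collection, mode, alpha)
  }
  out
}
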