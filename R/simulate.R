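#' @importFrom stats rbinom rlnorm rnorm runif setNames
NULL

#' Configuration for the synthetic collection generator
#'
#' Returns the full parameter set driving [simulateCollection()], with
#' defaults chosen to emulate the statistical structure of a screening
#' study of 101 diazotrophic/N-scavenging strains isolated from three
#' soil managements, three isolation sources and five semisolid N-free
#' media, with one dominant genus and stated trait detection rates.
#' Every argument can be overridden.
#'
#' Defaults of note (units in parentheses):
#' * `genus_probs`: one dominant genus (*Rhizobium*, share 0.58).
#' * `trait_detect`: detection probabilities IAA 0.485, FePO4 0.713,
#'   AlPO4 0.435, siderophore 0.435.
#' * `trait_lognormal`: positive trait values are log-normal with the
#'   listed means (IAA 33.1 ug/mg protein; FePO4 6.36 and AlPO4 3.85
#'   solubilized P; siderophore index 1 + log-normal with mean 0.7) —
#'   right-skewed, matching the order-of-magnitude spread of observed
#'   ranges.
#' * fingerprints: `n_band_clusters` latent profile prototypes,
#'   `bands_per_profile` bands (200-5000 bp), relative band jitter
#'   `band_jitter` (fraction, well below the 2% matching tolerance),
#'   `band_keep_prob` and `private_band_rate` controlling within-cluster
#'   profile variation, `n_clone_pairs` planted near-clonal pairs.
#' * biomass: `r` = 5 replicates; control means per species set to the
#'   centre of the observed control bands (tomato RDW 0.25 / SDW 0.83,
#'   lulo RDW 0.12 / SDW 0.315 g per plant); per-strain inoculation
#'   effects normal with SD `effect_sd` (fraction of the control mean);
#'   residual coefficient of variation `residual_cv`.
#' * dilutions: `n_samples` series at true densities `lambda_range`
#'   (cells/g, log-uniform), `amounts_g` per-vial material amounts,
#'   `n_vials` vials per dilution (a 3-dilution x 3-vial design).
#'
#' @param n_strains number of strains (default 101).
#' @param source_probs,soil_probs,medium_probs,genus_probs named
#'   probability vectors over the controlled vocabularies.
#' @param trait_detect named detection probabilities for
#'   `iaa`, `fepo4`, `alpo4`, `siderophore_index`.
#' @param trait_lognormal named list of `c(mean, sdlog)` per trait; the
#'   siderophore entry parameterizes `siderophore_index - 1`.
#' @param n_band_clusters,bands_per_profile,band_jitter,band_keep_prob,private_band_rate,n_clone_pairs
#'   fingerprint generator controls.
#' @param r,control_means,effect_sd,residual_cv biomass design controls;
#'   `control_means` is a list per species with `rdw` and `sdw` entries.
#' @param n_samples,lambda_range,amounts_g,n_vials dilution design.
#' @param seed master seed; one RNG stream per component is derived from
#'   it so that components do not perturb one another.
#' @return a list of class `dzSimConfig`.
#' @seealso [simulateCollection()]
#' @export
simulationConfig <- function(n_strains = 101,
                             source_probs = c(BS = 26, TR = 42, LR = 33) / 101,
                             soil_probs = c(SF = 34, CH = 27, ORG = 40) / 101,
                             medium_probs = c(JMV = 49, NFb = 6, JNFb = 31,
                                              LGI = 13, `LGI-P` = 2) / 101,
                             genus_probs = c(Rhizobium = 59, Pseudomonas = 12,
                                             Burkholderia = 11, Enterobacter = 5,
                                             Variovorax = 4, Cupriavidus = 3,
                                             Stenotrophomonas = 2, Caulobacter = 1,
                                             Novosphingobium = 1, Pelomonas = 1,
                                             Xanthomonas = 1, unclassified = 1) / 101,
                             trait_detect = c(iaa = 0.485, fepo4 = 0.713,
                                              alpo4 = 0.435,
                                              siderophore_index = 0.435),
                             trait_lognormal = list(
                               iaa = c(mean = 33.1, sdlog = 1.05),
                               fepo4 = c(mean = 6.36, sdlog = 1.15),
                               alpo4 = c(mean = 3.85, sdlog = 0.85),
                               siderophore_index = c(mean = 0.7, sdlog = 0.9)),
                             n_band_clusters = 20,
                             bands_per_profile = 12,
                             band_jitter = 0.002,
                             band_keep_prob = 0.95,
                             private_band_rate = 0.3,
                             n_clone_pairs = 5,
                             r = 5,
                             control_means = list(
                               tomato = c(rdw = 0.25, sdw = 0.83),
                               lulo = c(rdw = 0.12, sdw = 0.315)),
                             effect_sd = 0.15,
                             residual_cv = 0.08,
                             n_samples = 9,
                             lambda_range = c(1e4, 3e5),
                             amounts_g = c(1e-4, 1e-5, 1e-6),
                             n_vials = 3,
                             seed = 1) {
  cfg <- list(n_strains = n_strains, source_probs = source_probs,
              soil_probs = soil_probs, medium_probs = medium_probs,
              genus_probs = genus_probs, trait_detect = trait_detect,
              trait_lognormal = trait_lognormal,
              n_band_clusters = n_band_clusters,
              bands_per_profile = bands_per_profile,
              band_jitter = band_jitter, band_keep_prob = band_keep_prob,
              private_band_rate = private_band_rate,
              n_clone_pairs = n_clone_pairs, r = r,
              control_means = control_means, effect_sd = effect_sd,
              residual_cv = residual_cv, n_samples = n_samples,
              lambda_range = lambda_range, amounts_g = amounts_g,
              n_vials = n_vials, seed = seed)
  probs <- c(cfg$source_probs, cfg$soil_probs, cfg$medium_probs,
             cfg$genus_probs, cfg$trait_detect)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$r < 2) stop("biomass design needs r >= 2 replicates")
  if (any(cfg$lambda_range <= 0)) stop("lambda must be positive")
  if (cfg$n_strains < 0) stop("n_strains must be non-negative")
  if (cfg$n_clone_pairs * 2 > cfg$n_strains && cfg$n_strains > 0) {
    stop("infeasible config: n_clone_pairs exceeds n_strains / 2")
  }
  class(cfg) <- "dzSimConfig"
  cfg
}

## Independent sub-seeds per component, derived deterministically from
## the master seed (kept below 2^31).
componentSeeds <- function(seed) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 5L),
           c("strains", "traits", "bands", "biomass", "dilutions"))
}

#' Simulate one serial-dilution outcome series
#'
#' Each vial inoculated with `m` grams of material from a suspension of
#' true density `lambda` (cells/g) turns positive independently with
#' probability `1 - exp(-lambda * m)` (Poisson presence).
#'
#' @param lambda true density, cells per gram (>= 0).
#' @param amounts_g strictly decreasing vector of per-vial amounts (g).
#' @param n_vials vials per dilution level.
#' @param sample_id label carried into the output.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return data.frame in the dilution-table dialect (`sample_id`,
#'   `amount_g`, `n_vials`, `n_positive`).
#' @examples
#' simulateDilutionSeries(5e4, c(1e-4, 1e-5, 1e-6), 3, seed = 1)
#' @export
simulateDilutionSeries <- function(lambda, amounts_g, n_vials,
                                   sample_id = "S1", seed = NULL) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (any(amounts_g <= 0)) stop("amounts must be positive")
  if (any(diff(amounts_g) >= 0)) stop("amounts must be strictly decreasing")
  if (!is.null(seed)) set.seed(seed)
  p <- -expm1(-lambda * amounts_g)
  data.frame(sample_id = sample_id, amount_g = amounts_g,
             n_vials = as.integer(n_vials),
             n_positive = rbinom(length(amounts_g), n_vials, p),
             stringsAsFactors = FALSE)
}

rTraitPositive <- function(n, par) {
  mu <- log(par[["mean"]]) - par[["sdlog"]]^2 / 2
  rlnorm(n, meanlog = mu, sdlog = par[["sdlog"]])
}

#' Generate a synthetic strain collection with known ground truth
#'
#' Draws a full [StrainCollection-class] — provenance records, trait
#' measurements with non-detections, clustered band profiles with planted
#' clone pairs, replicated greenhouse biomass with per-strain effects,
#' and MPN dilution series — under the statistical structure configured
#' by [simulationConfig()], together with the latent truth needed to
#' score recovery of every downstream stage.
#'
#' Components draw from separate RNG streams derived from the master
#' seed, so e.g. changing the biomass design leaves the simulated traits
#' untouched. The `components` argument restricts generation to a subset
#' (the others come back empty), which keeps replicate studies cheap.
#'
#' @param config a `dzSimConfig` from [simulationConfig()].
#' @param components character subset of
#'   `c("traits", "bands", "biomass", "dilutions")`.
#' @return list with elements `collection` (a [StrainCollection-class])
#'   and `truth`: per-strain true trait values and detection flags
#'   (`trait_values`, `trait_detected`), band-cluster labels
#'   (`band_cluster`) and clone pairings (`clone_pairs`), true biomass
#'   effects as fractions of the control mean (`biomass_effect`), and
#'   true densities per dilution sample (`lambda`).
#' @examples
#' sim <- simulateCollection(simulationConfig(n_strains = 12, seed = 7))
#' sim$collection
#' @export
simulateCollection <- function(config = simulationConfig(),
                               components = c("traits", "bands", "biomass",
                                              "dilutions")) {
  stopifnot(inherits(config, "dzSimConfig"))
  components <- match.arg(components, several.ok = TRUE)
  seeds <- componentSeeds(config$seed)
  n <- config$n_strains

  truth <- list(trait_values = NULL, trait_detected = NULL,
                band_cluster = NULL, clone_pairs = list(),
                biomass_effect = NULL, lambda = NULL)
  if (n == 0) {
    return(list(collection = StrainCollection(), truth = truth))
  }

  ## provenance records -------------------------------------------------
  set.seed(seeds[["strains"]])
  ids <- sprintf("SYN%03d", seq_len(n))
  strains <- data.frame(
    strain_id = ids,
    source = sample(names(config$source_probs), n, TRUE, config$source_probs),
    soil = sample(names(config$soil_probs), n, TRUE, config$soil_probs),
    medium = sample(names(config$medium_probs), n, TRUE, config$medium_probs),
    genus = sample(names(config$genus_probs), n, TRUE, config$genus_probs),
    stringsAsFactors = FALSE)

  traits <- emptyTraitFrame()
  bands <- list()
  biomass <- emptyBiomassFrame()
  dilutions <- emptyDilutionFrame()

  ## trait measurements -------------------------------------------------
  if ("traits" %in% components) {
    set.seed(seeds[["traits"]])
    tnames <- names(config$trait_detect)
    det <- vapply(tnames, function(tn) {
      runif(n) < config$trait_detect[[tn]]
    }, logical(n))
    det <- matrix(det, nrow = n, dimnames = list(ids, tnames))
    val <- matrix(NA_real_, n, length(tnames), dimnames = list(ids, tnames))
    for (tn in tnames) {
      k <- sum(det[, tn])
      if (k) {
        v <- rTraitPositive(k, config$trait_lognormal[[tn]])
        if (tn == "siderophore_index") v <- 1 + v
        val[det[, tn], tn] <- v
      }
    }
    traits <- data.frame(strain_id = ids, iaa = val[, "iaa"],
                         fepo4 = val[, "fepo4"], alpo4 = val[, "alpo4"],
                         siderophore_index = val[, "siderophore_index"],
                         stringsAsFactors = FALSE)
    rownames(traits) <- NULL
    truth$trait_values <- val
    truth$trait_detected <- det
  }

  ## band profiles ------------------------------------------------------
  if ("bands" %in% components) {
    set.seed(seeds[["bands"]])
    ncl <- min(config$n_band_clusters, n)
    ## bands are drawn log-uniform on 200-5000 bp with a guaranteed 5%
    ## relative spacing: fragments closer than the matching tolerance
    ## are not resolvable on a gel, so prototypes never carry them
    drawBands <- function(k, lo = log(200), hi = log(5000),
                          min_gap = log(1.05)) {
      slack <- (hi - lo) - (k - 1) * min_gap
      pos <- lo + sort(runif(k)) * slack + (seq_len(k) - 1) * min_gap
      round(exp(pos))
    }
    prototypes <- lapply(seq_len(ncl), function(i) {
      drawBands(config$bands_per_profile)
    })
    cluster <- sort(rep_len(seq_len(ncl), n))
    makeProfile <- function(proto) {
      keep <- runif(length(proto)) < config$band_keep_prob
      b <- proto[keep]
      n_priv <- rbinom(1, 3, config$private_band_rate / 3)
      if (n_priv) {
        cand <- round(exp(runif(n_priv, log(200), log(5000))))
        # keep private bands resolvable from the inherited ones
        for (x in cand) {
          if (all(abs(log(x) - log(b)) >= log(1.05))) b <- c(b, x)
        }
      }
      b <- b * (1 + runif(length(b), -config$band_jitter, config$band_jitter))
      sort(unique(round(b)))
    }
    bands <- lapply(cluster, function(ci) makeProfile(prototypes[[ci]]))
    names(bands) <- ids
    clone_pairs <- list()
    if (config$n_clone_pairs > 0) {
      pick <- sample(n, 2L * config$n_clone_pairs)
      for (p in seq_len(config$n_clone_pairs)) {
        a <- pick[2L * p - 1L]
        b <- pick[2L * p]
        jit <- bands[[a]] * (1 + runif(length(bands[[a]]),
                                       -config$band_jitter, config$band_jitter))
        bands[[b]] <- sort(unique(round(jit)))
        cluster[b] <- cluster[a]
        clone_pairs[[p]] <- c(ids[a], ids[b])
      }
    }
    truth$band_cluster <- setNames(cluster, ids)
    truth$clone_pairs <- clone_pairs
  }

  ## greenhouse biomass -------------------------------------------------
  if ("biomass" %in% components) {
    set.seed(seeds[["biomass"]])
    species <- names(config$control_means)
    eff <- matrix(rnorm(n * length(species), 0, config$effect_sd),
                  nrow = n, dimnames = list(ids, species))
    rows <- vector("list", length(species))
    for (si in seq_along(species)) {
      sp <- species[si]
      cm <- config$control_means[[sp]]
      treat <- c(DZ_CONTROL, ids)
      fr <- c(0, eff[, sp])
      sp_rows <- lapply(seq_along(treat), function(ti) {
        mu_r <- cm[["rdw"]] * (1 + fr[ti])
        mu_s <- cm[["sdw"]] * (1 + fr[ti])
        data.frame(species = sp, treatment = treat[ti],
                   replicate = seq_len(config$r),
                   rdw = pmax(0, rnorm(config$r, mu_r,
                                       config$residual_cv * cm[["rdw"]])),
                   sdw = pmax(0, rnorm(config$r, mu_s,
                                       config$residual_cv * cm[["sdw"]])),
                   stringsAsFactors = FALSE)
      })
      rows[[si]] <- do.call(rbind, sp_rows)
    }
    biomass <- do.call(rbind, rows)
    rownames(biomass) <- NULL
    truth$biomass_effect <- eff
  }

  ## MPN dilution series ------------------------------------------------
  if ("dilutions" %in% components) {
    set.seed(seeds[["dilutions"]])
    lam <- exp(runif(config$n_samples, log(config$lambda_range[1]),
                     log(config$lambda_range[2])))
    sids <- sprintf("SAMPLE%02d", seq_len(config$n_samples))
    ser <- lapply(seq_len(config$n_samples), function(i) {
      simulateDilutionSeries(lam[i], config$amounts_g, config$n_vials,
                             sample_id = sids[i])
    })
    dilutions <- do.call(rbind, ser)
    truth$lambda <- setNames(lam, sids)
  }

  collection <- StrainCollection(strains = strains, traits = traits,
                                 biomass = biomass, dilutions = dilutions,
                                 bands = bands)
  list(collection = collection, truth = truth)
}
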