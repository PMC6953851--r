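# Shared fixture builders; everything is generated in code at test time.

makeStrains <- function(ids, source = "BS", soil = "SF", medium = "JMV",
                        genus = "Rhizobium") {
  if (!length(ids)) {
    return(data.frame(strain_id = character(), source = character(),
                      soil = character(), medium = character(),
                      genus = character(), stringsAsFactors = FALSE))
  }
  data.frame(strain_id = ids, source = source, soil = soil,
             medium = medium, genus = genus, stringsAsFactors = FALSE)
}

# Balanced one-way biomass design: one row per replicate, both responses.
makeBiomass <- function(means, r = 5, sd = 0.1, species = "tomato",
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  treat <- names(means)
  data.frame(species = species,
             treatment = rep(treat, each = r),
             replicate = rep(seq_len(r), length(treat)),
             rdw = rnorm(r * length(treat), rep(means, each = r), sd),
             sdw = rnorm(r * length(treat), rep(means, each = r), sd),
             stringsAsFactors = FALSE)
}

# A small complete collection for IO round trips.
makeTinyCollection <- function() {
  strains <- makeStrains(c("01T", "02S"), source = c("TR", "BS"),
                         soil = c("CH", "ORG"), medium = c("JMV", "NFb"),
                         genus = c("Rhizobium", "Enterobacter"))
  traits <- data.frame(strain_id = c("01T", "02S"),
                       iaa = c(12.5, NA), fepo4 = c(3.25, 8.125),
                       alpo4 = c(NA, 0), siderophore_index = c(1.5, NA),
                       stringsAsFactors = FALSE)
  biomass <- rbind(
    makeBiomass(c(CONTROL = 0.25, `01T` = 0.30, `02S` = 0.20), r = 3,
                sd = 0.02, species = "tomato", seed = 11),
    makeBiomass(c(CONTROL = 0.12, `01T` = 0.15, `02S` = 0.10), r = 3,
                sd = 0.02, species = "lulo", seed = 12))
  dilutions <- rbind(
    data.frame(sample_id = "S1", amount_g = c(1e-4, 1e-5, 1e-6),
               n_vials = 3L, n_positive = c(3L, 1L, 0L)),
    data.frame(sample_id = "S2", amount_g = c(1e-4, 1e-5, 1e-6),
               n_vials = 3L, n_positive = c(2L, 0L, 0L)))
  bands <- list(`01T` = c(150, 420, 980, 2500),
                `02S` = c(300, 610, 1200))
  aln <- Biostrings::DNAStringSet(c(`01T` = "ACGTACGTAC",
                                    `02S` = "ACGTTCGA-C"))
  StrainCollection(strains = strains, traits = traits, biomass = biomass,
                   dilutions = dilutions, bands = bands, alignment = aln)
}

# Adjusted Rand index between two labelings (independent of any package
# clustering code; used to score cluster recovery).
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

expect_identical_collection <- function(x, y) {
  expect_equal(strainInfo(x), strainInfo(y))
  expect_equal(traitValues(x), traitValues(y), tolerance = 1e-9)
  expect_equal(biomassData(x), biomassData(y), tolerance = 1e-9)
  expect_equal(dilutionData(x), dilutionData(y), tolerance = 1e-9)
  expect_equal(bandProfiles(x), bandProfiles(y), tolerance = 1e-9)
  expect_equal(as.character(alignment16S(x)), as.character(alignment16S(y)))
}
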