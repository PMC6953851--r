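test_that("trait summary counts positives and their co-occurrence", {
  traits <- data.frame(
    strain_id = c("A", "B", "C"),
    iaa = c(10, 5, NA),
    fepo4 = c(NA, 2, NA),
    alpo4 = c(NA, NA, NA),
    siderophore_index = c(NA, NA, NA))
  ts <- traitSummary(traits)
  expect_identical(ts$n_at_least_one, 2L)
  expect_identical(ts$n_multi, 1L)
  expect_identical(unname(ts$co_occurrence["iaa"]), 1L)
  expect_identical(unname(ts$co_occurrence["iaa+fepo4"]), 1L)
  expect_identical(unname(ts$co_occurrence["(none)"]), 1L)
  pt <- ts$per_trait
  expect_equal(pt$mean[pt$trait == "iaa"], 7.5)
  expect_identical(pt$n_positive[pt$trait == "alpo4"], 0L)
  expect_true(is.na(pt$mean[pt$trait == "alpo4"]))
  # a detected zero is stored but does not count as positive
  traits$fepo4[1] <- 0
  expect_identical(traitSummary(traits)$co_occurrence[["iaa"]], 1L)
})

test_that("trait scores bin values around the positive-strain mean", {
  # band mode around mean 3.85: bounds 0.65*3.85 = 2.5025, 1.35*3.85 = 5.1975
  expect_identical(traitScore(NA, 3.85), 0L)
  expect_identical(traitScore(0, 3.85), 0L)
  expect_identical(traitScore(1.2, 3.85), 1L)
  expect_identical(traitScore(3.0, 3.85), 2L)
  expect_identical(traitScore(17.05, 3.85), 3L)
  # boundary values take the higher bin
  expect_identical(traitScore(0.65 * 3.85, 3.85), 2L)
  expect_identical(traitScore(1.35 * 3.85, 3.85), 3L)
  # literal mode uses 0.35 and 0.70 of the mean
  expect_identical(traitScore(1.2, 3.85, mode = "literal"), 1L)
  expect_identical(traitScore(1.5, 3.85, mode = "literal"), 2L)
  expect_identical(traitScore(3.0, 3.85, mode = "literal"), 3L)
  expect_error(traitScore(-1, 3.85), ">= 0")
  expect_error(traitScore(1, 0), "positive")
  # monotone: a larger value never scores lower
  v <- sort(runif(50, 0, 10))
  expect_identical(traitScore(v, 3.85), cummax(traitScore(v, 3.85)))
})

test_that("biometric scores compare Scott-Knott clusters to the control", {
  d <- makeBiomass(c(CONTROL = 1, UP = 1.6, SAME = 1.02, DOWN = 0.4),
                   r = 5, sd = 0.05, seed = 9)
  g <- scottKnott(oneWayAnova(d, "tomato", "rdw"))
  expect_identical(biometricScore("UP", g), 2L)
  expect_identical(biometricScore("SAME", g), 1L)
  expect_identical(biometricScore("DOWN", g), 0L)
  expect_identical(biometricScore("CONTROL", g), 1L)
  expect_error(biometricScore("MISSING", g), "absent")

  # fixed-cutoff replay of published bounds
  expect_identical(cutoffScore(0.30, 0.23, 0.27), 2L)
  expect_identical(cutoffScore(0.70, 0.79, 0.87), 0L)
  expect_identical(cutoffScore(0.25, 0.23, 0.27), 1L)
  expect_identical(cutoffScore(c(0.23, 0.27), 0.23, 0.27), c(1L, 2L))
})

test_that("bonitur totals, dense ranks and the potential flag assemble correctly", {
  ref <- referenceBoniturScores()
  out <- boniturFromScores(ref)
  expect_equal(out$total, out$printed_total)
  expect_identical(out$rank, as.integer(out$printed_rank))
  expect_true(all(out$total >= 0 & out$total <= 20))
  expect_true(all(out$biotech_potential))

  expect_identical(rankStrains(c(14, 12, 12, 11)), c(1L, 2L, 2L, 3L))
  expect_identical(rankStrains(20), 1L)
  expect_identical(rankStrains(c(5, 5, 5)), c(1L, 1L, 1L))
  expect_identical(rankStrains(numeric()), integer())

  bad <- ref
  bad$iaa[1] <- 4
  expect_error(boniturFromScores(bad), "out of range")
  bad2 <- ref
  bad2$tomato_rdw[1] <- 3
  expect_error(boniturFromScores(bad2), "out of range")
})

test_that("increasing one trait value never lowers the bonitur total", {
  sim <- simulateCollection(simulationConfig(n_strains = 15, seed = 10))
  sc <- sim$collection
  bt <- boniturTable(sc)
  tm <- attr(bt, "trait_means")
  tr <- traitValues(sc)
  i <- which(!is.na(tr$iaa))[1]
  tr2 <- tr
  tr2$iaa[i] <- tr2$iaa[i] * 10
  sc2 <- StrainCollection(strains = strainInfo(sc), traits = tr2,
                          biomass = biomassData(sc),
                          dilutions = dilutionData(sc),
                          bands = bandProfiles(sc))
  # score the perturbed strain against the *original* trait means so the
  # comparison isolates the strain's own value
  s_old <- traitScore(tr$iaa[i], tm[["iaa"]])
  s_new <- traitScore(tr2$iaa[i], tm[["iaa"]])
  expect_gte(s_new, s_old)
  bt2 <- boniturTable(sc2)
  expect_true(all(bt2$total >= 0 & bt2$total <= 20, na.rm = TRUE))
})

test_that("end-to-end: planted all-maximal strains occupy the top ranks", {
  cfg <- simulationConfig(n_strains = 24, seed = 6)
  sim <- simulateCollection(cfg)
  sc <- sim$collection
  tr <- traitValues(sc)
  bm <- biomassData(sc)
  elite <- c("SYN001", "SYN002")
  # plant maximal traits and strong positive biomass responses
  for (v in c("iaa", "fepo4", "alpo4", "siderophore_index")) {
    tr[[v]][tr$strain_id %in% elite] <- max(tr[[v]], na.rm = TRUE) * 3
  }
  for (sp in c("tomato", "lulo")) {
    ctrl <- bm$species == sp & bm$treatment == "CONTROL"
    mu <- mean(c(bm$rdw[ctrl], bm$sdw[ctrl]))
    sel <- bm$species == sp & bm$treatment %in% elite
    bm$rdw[sel] <- bm$rdw[sel] + 2 * mu
    bm$sdw[sel] <- bm$sdw[sel] + 2 * mu
  }
  sc2 <- StrainCollection(strains = strainInfo(sc), traits = tr,
                          biomass = bm, dilutions = dilutionData(sc),
                          bands = bandProfiles(sc))
  bt <- boniturTable(sc2)
  expect_setequal(bt$strain_id[bt$rank == 1], elite)
  expect_equal(bt$total[1], 20)
})

test_that("genus distribution percentages and class rollups are conserved", {
  ref <- referenceGenusCounts()
  strains <- makeStrains(sprintf("G%03d", seq_len(sum(ref$n))),
                         genus = rep(ref$genus, ref$n))
  gd <- genusDistribution(strains)
  expect_identical(sum(gd$genera$n), 101L)
  expect_equal(gd$genera$pct[gd$genera$genus == "Rhizobium"], 58.4)
  expect_identical(sum(gd$classes$n), 101L)
  alpha <- gd$classes$n[gd$classes$class == "Alphaproteobacteria"]
  expect_identical(alpha, 61L)
  empty <- genusDistribution(makeStrains(character()))
  expect_identical(nrow(empty$genera), 0L)
})

test_that("screenStrains runs every stage present in the collection", {
  sim <- simulateCollection(simulationConfig(n_strains = 20, seed = 14))
  rep <- screenStrains(sim$collection)
  expect_named(rep, c("genus", "traits", "mpn", "fingerprint", "bonitur"),
               ignore.order = TRUE)
  expect_identical(nrow(rep$mpn), 9L)
  expect_true(all(rep$bonitur$total <= 20, na.rm = TRUE))
  expect_identical(length(rep$fingerprint$groups), 20L)
})
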