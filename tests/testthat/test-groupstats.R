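test_that("one-way ANOVA reproduces the textbook decomposition", {
  d <- data.frame(species = "tomato",
                  treatment = rep(c("A", "B"), each = 3),
                  replicate = rep(1:3, 2),
                  rdw = c(1, 2, 3, 4, 5, 6), sdw = 0)
  a <- oneWayAnova(d, "tomato", "rdw")
  expect_equal(a$F, 13.5)
  expect_equal(a$mse, 1)
  expect_equal(a$df_error, 4)
  expect_equal(unname(a$means), c(2, 5))

  # all equal -> F = 0
  d0 <- d
  d0$rdw <- 2
  expect_equal(oneWayAnova(d0, "tomato", "rdw")$F, 0)

  # permuting group labels conserves SS_total = SS_b + ss_w
  ss <- function(x) {
    with(x, sum((rdw - mean(rdw))^2))
  }
  a1 <- oneWayAnova(d, "tomato", "rdw")
  d_perm <- d
  d_perm$treatment <- rev(d$treatment)
  a2 <- oneWayAnova(d_perm, "tomato", "rdw")
  ssb <- function(a, d) ss(d) - a$mse * a$df_error
  expect_equal(ssb(a1, d) + a1$mse * a1$df_error,
               ssb(a2, d_perm) + a2$mse * a2$df_error)

  expect_error(oneWayAnova(d[d$treatment == "A", ], "tomato", "rdw"),
               "2 groups")
  expect_error(oneWayAnova(d[-(1:2), ], "tomato", "rdw"), "replicates")
})

test_that("Scott-Knott separates two clear tiers and not equal means", {
  a <- dzAnovaStub(c(A = 1.0, B = 1.1, C = 9.0, D = 9.2), mse = 0.25,
                   r = 5, nu = 16)
  g <- scottKnott(a)
  expect_identical(unname(g$group[match(c("C", "D"), g$treatment)]),
                   c(1L, 1L))
  expect_identical(unname(g$group[match(c("A", "B"), g$treatment)]),
                   c(2L, 2L))
  expect_identical(g$label[1], "a")

  eq <- dzAnovaStub(c(A = 2, B = 2, C = 2), mse = 0.25, r = 5, nu = 12)
  expect_identical(max(scottKnott(eq)$group), 1L)

  # alpha -> 0 never splits
  expect_identical(max(scottKnott(a, alpha = 1e-12)$group), 1L)
})

test_that("Scott-Knott groups are contiguous and monotone in alpha", {
  set.seed(77)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    a <- dzAnovaStub(setNames(rnorm(k, 0, 1.5), paste0("t", 1:k)),
                     mse = 1, r = 5, nu = 4 * k)
    gs <- lapply(c(0.01, 0.05, 0.20), function(al) scottKnott(a, al))
    for (g in gs) {
      # contiguity: group ids along descending means never revisit
      expect_identical(g$group, cummax(g$group))
    }
    n_groups <- vapply(gs, function(g) max(g$group), integer(1))
    expect_true(all(diff(n_groups) >= 0))
  }
})

test_that("recursive Scott-Knott equals the brute-force split search (k <= 6)", {
  set.seed(123)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    means <- setNames(round(rnorm(k, 0, 1), 3), paste0("t", 1:k))
    mse <- runif(1, 0.1, 2)
    a <- dzAnovaStub(means, mse = mse, r = 5, nu = 5 * k)
    mine <- scottKnott(a)
    oracle <- skOracle(means, mse, 5, 5 * k)
    expect_identical(setNames(mine$group, mine$treatment),
                     oracle[mine$treatment])
  }
})

test_that("null simulations split at close to the nominal rate", {
  set.seed(42)
  n_sim <- 500
  splits <- vapply(seq_len(n_sim), function(i) {
    d <- data.frame(species = "tomato",
                    treatment = rep(letters[1:5], each = 5),
                    replicate = rep(1:5, 5),
                    rdw = rnorm(25), sdw = 0)
    max(scottKnott(oneWayAnova(d, "tomato", "rdw"))$group) > 1
  }, logical(1))
  rate <- mean(splits)
  # alpha = 0.05 within ~3 Monte-Carlo SDs (sqrt(.05*.95/500) ~ 0.01)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("two well-separated effect tiers are recovered", {
  # single-strain tiers: the exact 2-group partition, every seed
  hits <- vapply(1:100, function(s) {
    d <- makeBiomass(c(LOW = 1, HIGH = 1.5), r = 5, sd = 0.1, seed = s)
    max(scottKnott(oneWayAnova(d, "tomato", "rdw"))$group) == 2
  }, logical(1))
  expect_gte(mean(hits), 0.99)

  # multi-strain tiers >= 5 residual SDs apart: no group ever mixes the
  # tiers (within-tier subdivision can occur at rate ~alpha by design)
  pure <- vapply(1:100, function(s) {
    means <- c(a1 = 1, a2 = 1, a3 = 1, b1 = 1.5, b2 = 1.5, b3 = 1.5)
    d <- makeBiomass(means, r = 5, sd = 0.1, seed = 1000 + s)
    g <- scottKnott(oneWayAnova(d, "tomato", "rdw"))
    tier <- substr(g$treatment, 1, 1)
    !any(vapply(unique(g$group), function(gr) {
      length(unique(tier[g$group == gr])) > 1
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(pure), 0.99)
})

test_that("pearson correlation matches hand computations", {
  expect_equal(pearsonCorrelation(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(1, 0, 1))$r, 0)
  out <- pearsonCorrelation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(out$r, 0.6)
  expect_true(out$p > 0 && out$p < 1)
  expect_error(pearsonCorrelation(c(1, 2, 3), c(2, 2, 2)), "variance")
  expect_error(pearsonCorrelation(1:3, 1:4), "equal length")
})
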