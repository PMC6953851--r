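# Closed-form K2P oracle values computed by hand from transition /
# transversion counts: d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q).
test_that("K2P distance matches the closed form and handles exclusions", {
  expect_equal(k2pDistance("ACGT", "ACGT"), 0)
  # one transversion among 4 sites: P = 0, Q = 0.25
  expect_equal(k2pDistance("ACGT", "ACGA"),
               -0.5 * log(0.75) - 0.25 * log(0.5), tolerance = 1e-12)
  # one A<->G transition among 4 sites: P = 0.25, Q = 0
  expect_equal(k2pDistance("ACGT", "GCGT"),
               -0.5 * log(0.5), tolerance = 1e-12)
  # gap and N sites are excluded pairwise
  expect_equal(k2pDistance("AC-GTN", "ACTGTA"), 0)
  expect_error(k2pDistance("----", "ACGT"), "usable")
  expect_error(k2pDistance("ACGT", "ACG"), "equal length")
  # saturation: every site a transversion
  expect_error(k2pDistance("AAAA", "CCCC"), "saturated")
})

test_that("K2P agrees with the reference distance implementation", {
  set.seed(31)
  n <- 8
  L <- 300
  base <- sample(c("A", "C", "G", "T"), L, TRUE)
  m <- t(vapply(seq_len(n), function(i) {
    s <- base
    mut <- sample(L, 25)
    s[mut] <- sample(c("A", "C", "G", "T"), 25, TRUE)
    s
  }, character(L)))
  rownames(m) <- paste0("t", seq_len(n))
  d <- k2pMatrix(m)
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(d, ref[rownames(d), colnames(d)], tolerance = 1e-10)

  # small-divergence behavior: d ~ p for p -> 0
  a <- paste(rep("A", 1000), collapse = "")
  b <- paste(c(rep("A", 995), "G", "G", "C", "C", "T"), collapse = "")
  p <- 5 / 1000
  expect_lt(abs(k2pDistance(a, b) - p) / p, 0.01)
})

test_that("neighbor joining recovers additive trees exactly", {
  # fixed 4-taxon tree ((A:1,B:2):1,(C:3,D:4)) by path-summation oracle
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 6
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 7
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- njTree(D)
  expect_s3_class(tr, "phylo")
  pd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(pd, D, tolerance = 1e-10)

  # random additive trees up to 12 taxa
  for (s in 1:5) {
    set.seed(s)
    n <- sample(5:12, 1)
    true <- ape::unroot(ape::rtree(n))
    Dt <- ape::cophenetic.phylo(true)
    est <- njTree(Dt)
    expect_equal(as.numeric(ape::dist.topo(est, true)), 0)
    expect_equal(ape::cophenetic.phylo(est)[rownames(Dt), colnames(Dt)], Dt,
                 tolerance = 1e-8)
  }
})

test_that("three taxa resolve in closed form and duplicates give a zero cherry", {
  ids <- c("A", "B", "C")
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, dimnames = list(ids, ids))
  tr <- njTree(D)
  pd <- ape::cophenetic.phylo(tr)[ids, ids]
  expect_equal(pd, D, tolerance = 1e-10)

  D2 <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), 3, dimnames = list(ids, ids))
  tr2 <- njTree(D2)
  cherry <- ape::cophenetic.phylo(tr2)["A", "B"]
  expect_equal(unname(cherry), 0, tolerance = 1e-10)
  expect_true(all(tr2$edge.length >= 0))

  expect_error(njTree(matrix(0, 2, 2)), "3 taxa")
})

test_that("negative NJ branch estimates are clamped but retained raw", {
  ids <- paste0("t", 1:4)
  set.seed(4)
  # a noisy, non-additive matrix prone to negative edges
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D[upper.tri(D)] <- c(0.1, 0.11, 0.5, 0.12, 0.5, 0.5)
  D <- D + t(D)
  tr <- njTree(D)
  raw <- attr(tr, "raw_edge_length")
  expect_true(all(tr$edge.length >= 0))
  expect_equal(pmax(raw, 0), tr$edge.length)
})

test_that("bootstrap support is deterministic and saturates on clean signal", {
  set.seed(5)
  L <- 200
  base <- sample(c("A", "C", "G", "T"), L, TRUE)
  m <- matrix(rep(base, 6), nrow = 6, byrow = TRUE,
              dimnames = list(paste0("t", 1:6), NULL))
  m[1:3, 1:40] <- "A"  # forty fixed differences split t1-t3 from t4-t6
  m[4:6, 1:40] <- "G"
  for (i in 1:6) {
    idx <- sample(41:L, 12)
    m[i, idx] <- sample(c("A", "C", "G", "T"), 12, TRUE)
  }
  bs <- bootstrapSupport(m, n_reps = 80, seed = 9)
  expect_identical(bs$n_used + bs$n_skipped, 80L)
  # the planted bipartition edge carries full support
  expect_true(any(bs$support >= 0.99, na.rm = TRUE))
  bs2 <- bootstrapSupport(m, n_reps = 80, seed = 9)
  expect_identical(bs$support, bs2$support)

  one <- bootstrapSupport(m, n_reps = 1, seed = 2)
  expect_true(all(one$support %in% c(0, 1) | is.na(one$support)))
})

test_that("newick write-read-write is idempotent", {
  sim <- njTree(ape::cophenetic.phylo(ape::unroot(ape::rtree(7))))
  f1 <- withr::local_tempfile(fileext = ".nwk")
  f2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(sim, f1)
  back <- ape::read.tree(f1)
  ape::write.tree(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})
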