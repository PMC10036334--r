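# Period slicing, masked-CV rank selection, stability-selected NNMF.

mkAdjusted <- function(Tn = 12, n = 4L, seed = 1) {
  set.seed(seed)
  pg <- periodGrid(voicesPerOctave = 2, periodMin = 36,
                   periodMax = 36 * 2^(Tn / 2))
  new("PeriodogramTensor", grid = jidGrid(nSteps = n), periodGrid = pg,
      power = matrix(rnorm(length(periods(pg)) * n * n),
                     length(periods(pg)), n * n),
      kind = "adjusted")
}

test_that("slice-reshape retains the band, shifts to zero, and round-trips", {
  adj <- mkAdjusted()
  ph <- periods(adj)
  lo <- ph[3] / 24; hi <- ph[10] / 24
  rm <- sliceReshape(adj, lo, hi)
  expect_identical(nrow(rm@values), 8L)
  expect_equal(rm@periods, ph[3:10])
  expect_equal(min(rm@values), 0)
  # round trip: adding the shift back recovers the tensor slice, and the
  # raster order matches the 3-D view
  expect_equal(rm@values + rm@shift, adj@power[3:10, ], tolerance = 1e-12)
  pa <- powerArray(adj)
  n <- 4L
  for (b in c(1, 7, 16)) {
    r <- (b - 1) %% n + 1; cc <- (b - 1) %/% n + 1
    expect_equal(rm@values[, b] + rm@shift, pa[r, cc, 3:10],
                 tolerance = 1e-12)
  }
  expect_error(sliceReshape(adj, 1000, 2000), "empty period slice")
})

test_that("masked CV recovers a planted rank and tie-breaks to parsimony", {
  set.seed(4)
  W0 <- matrix(rexp(60 * 4), 60, 4)
  H0 <- matrix(rexp(4 * 80), 4, 80)
  A <- W0 %*% H0
  A <- A + matrix(rnorm(length(A), sd = 0.01 * mean(A)), nrow(A))
  A[A < 0] <- 0
  sel <- selectRank(A, ranks = 2:6, reps = 3, seed = 7, maxIter = 80)
  expect_identical(sel$rank, 4L)
  expect_identical(sel$cvCurve$rank, 2:6)
  # noiseless low rank: error ~ 0 for all ranks >= true; smallest wins
  A3 <- matrix(rexp(40 * 3), 40, 3) %*% matrix(rexp(3 * 50), 3, 50)
  sel3 <- selectRank(A3, ranks = 3:6, reps = 2, seed = 1, maxIter = 300)
  expect_identical(sel3$rank, 3L)
  expect_error(selectRank(A3, reps = 1), "at least 2")
})

test_that("decomposition similarity is symmetric and permutation-invariant", {
  set.seed(2)
  W <- matrix(rexp(30 * 4), 30, 4)
  expect_equal(decompositionSimilarity(W, W), 1, tolerance = 1e-12)
  Wp <- W[, c(3, 1, 4, 2)]
  expect_equal(decompositionSimilarity(W, Wp), 1, tolerance = 1e-12)
  expect_equal(decompositionSimilarity(W, 2.5 * Wp), 1, tolerance = 1e-12)
  V <- matrix(rexp(30 * 4), 30, 4)
  expect_equal(decompositionSimilarity(W, V),
               decompositionSimilarity(V, W), tolerance = 1e-12)
  expect_lt(decompositionSimilarity(W, matrix(rnorm(30 * 4), 30)), 0.6)
  # zero-variance component correlates as 0
  Wz <- W; Wz[, 2] <- 1
  expect_true(is.finite(decompositionSimilarity(W, Wz)))
  # disjoint-support orthogonal components: self-shuffle 1, noise ~ 0
  E <- diag(4)[rep(1:4, each = 8), ]
  expect_equal(decompositionSimilarity(E, E[, 4:1]), 1, tolerance = 1e-12)
})

test_that("starNNMF recovers planted factors and fixes the gauge", {
  set.seed(5)
  per <- seq(2.2 * 24, 28 * 24, length.out = 40)
  bump <- function(c0, w) exp(-(log(per / 24) - log(c0))^2 / (2 * w^2))
  W0 <- cbind(bump(7, 0.12), bump(25, 0.12))
  H0 <- matrix(rexp(2 * 100), 2, 100)
  A <- W0 %*% H0 + matrix(abs(rnorm(40 * 100, sd = 0.02)), 40)
  pgSlice <- new("RhythmMatrix", values = A, periods = per, shift = 0,
                 nSteps = 10)
  mrs <- starNNMF(pgSlice, rank = 2, restarts = 12, seed = 3)
  W <- metaRhythms(mrs)
  expect_true(all(W >= 0))
  expect_equal(unname(apply(W, 2, max)), c(1, 1), tolerance = 1e-9)
  # components ordered by peak period and matching the planted bumps
  expect_identical(order(per[apply(W, 2, which.max)]), 1:2)
  expect_gt(cor(W[, 1], W0[, 1]), 0.95)
  expect_gt(cor(W[, 2], W0[, 2]), 0.95)
  expect_gt(mrs@stability, 0.9)
  # reconstruction of the chosen run is no worse than typical
  expect_lt(sqrt(mean((A - W %*% metaBehaviors(mrs))^2)) / mean(A), 0.25)
})

test_that("starNNMF degenerate and tiny-restart contracts", {
  A <- matrix(rexp(20 * 15), 20, 15)
  expect_error(starNNMF(A * 0, 2, restarts = 2), "all-zero")
  # rank 1: every run identical up to scale -> stability 1
  r1 <- starNNMF(A, 1, restarts = 3, seed = 2)
  expect_equal(r1@stability, 1, tolerance = 1e-6)
  r2 <- starNNMF(A, 2, restarts = 2, seed = 2)
  expect_identical(r2@rank, 2)
})

test_that("two master seeds give matched meta-rhythms on the same input", {
  set.seed(6)
  W0 <- cbind(exp(-(1:30 - 8)^2 / 18), exp(-(1:30 - 22)^2 / 18))
  A <- W0 %*% matrix(rexp(2 * 60), 2, 60) +
    matrix(abs(rnorm(30 * 60, sd = 0.02)), 30)
  a <- starNNMF(A, 2, restarts = 10, seed = 101)
  b <- starNNMF(A, 2, restarts = 10, seed = 707)
  expect_gt(decompositionSimilarity(metaRhythms(a), metaRhythms(b)), 0.9)
})
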