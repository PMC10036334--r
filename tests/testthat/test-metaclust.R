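# Population clustering of meta-rhythms.

bumpCurve <- function(center, periodsD, width = 0.1, jitter = 0) {
  c0 <- center * (1 + jitter)
  exp(-(log(periodsD) - log(c0))^2 / (2 * width^2))
}

test_that("z-scoring standardizes, is affine-invariant, drops constants", {
  set.seed(1)
  x <- rnorm(50)
  z <- zscoreCurves(cbind(x, 3 * x + 7))
  expect_equal(colMeans(z$curves), c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(z$curves, 2, sd), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(z$curves[, 1], z$curves[, 2], tolerance = 1e-12)
  expect_warning(z2 <- zscoreCurves(cbind(x, rep(2, 50))), "constant")
  expect_identical(unname(z2$kept), 1L)
})

test_that("db4 features are deterministic and norm-preserving", {
  set.seed(2)
  v <- rnorm(64)
  f1 <- dwtFeatures(v)
  expect_identical(f1, dwtFeatures(v))
  expect_length(f1, 64)
  # orthonormal filter bank preserves the l2 norm at power-of-two lengths
  expect_equal(sum(f1^2), sum(v^2), tolerance = 1e-9)
  expect_length(dwtFeatures(rnorm(50)), 64)
})

test_that("two identical-curve groups separate perfectly at k = 2", {
  per <- seq(2.2, 28, length.out = 40)
  curves <- cbind(matrix(bumpCurve(7, per), 40, 8),
                  matrix(bumpCurve(25, per), 40, 8))
  # tiny noise so curves are not exactly constant duplicates
  set.seed(3)
  curves <- curves + matrix(rnorm(length(curves), sd = 1e-4), 40)
  rcs <- clusterMetaRhythms(curves, per * 24, maxK = 5, seed = 1)
  expect_equal(rcs@k, 2, ignore_attr = TRUE)
  truth <- rep(1:2, each = 8)
  expect_identical(length(unique(paste(rcs@assignments$cluster, truth))), 2L)
  expect_equal(rcs@peakPeriod, c(7, 25), tolerance = 0.8)
})

test_that("jittered rhythm families are recovered with high ARI", {
  skip_if_not_installed("mclust")
  per <- seq(2.2, 30, length.out = 50)
  set.seed(9)
  centers <- c(7, 14, 25)
  curves <- sapply(rep(centers, each = 30), function(c0)
    bumpCurve(c0, per, jitter = runif(1, -0.05, 0.05)) +
      rnorm(50, sd = 0.03))
  rcs <- clusterMetaRhythms(curves, per * 24, maxK = 8, seed = 4)
  expect_equal(rcs@k, 3, ignore_attr = TRUE)
  ari <- mclust::adjustedRandIndex(rcs@assignments$cluster,
                                   rep(1:3, each = 30))
  expect_gte(ari, 0.9)
  # assignment invariance to curve order
  o <- sample(ncol(curves))
  rcs2 <- clusterMetaRhythms(curves[, o], per * 24, maxK = 8, seed = 4)
  expect_equal(rcs2@k, 3, ignore_attr = TRUE)
  expect_gte(mclust::adjustedRandIndex(rcs2@assignments$cluster,
                                       rep(1:3, each = 30)[o]), 0.9)
})

test_that("peak and 95th-percentile range behave on known curve shapes", {
  per <- seq(2, 60, length.out = 120)
  g <- exp(-(per - 25)^2 / 18)
  pr <- peakAndRange(g, per)
  expect_equal(pr$peak, per[which.max(g)])
  expect_false(pr$incomplete)
  # symmetric bump -> symmetric range around the peak
  expect_equal(pr$rangeMax - pr$peak, pr$peak - pr$rangeMin, tolerance = 0.6)
  expect_true(pr$rangeMin <= pr$peak && pr$peak <= pr$rangeMax)
  # bimodal with taller 41-d mode: peak at 41, range may span both modes
  bi <- exp(-(per - 41)^2 / 20) + 0.95 * exp(-(per - 25)^2 / 20)
  prb <- peakAndRange(bi, per)
  expect_equal(prb$peak, per[which.max(bi)])
  expect_lte(prb$rangeMin, 41)
  # monotone curve abuts the edge -> incomplete
  mono <- peakAndRange(seq_along(per) / 10, per)
  expect_true(mono$incomplete)
  expect_equal(mono$peak, max(per))
  expect_error(peakAndRange(rep(1, 5), 1:5), "constant")
})

test_that("prevalence counts instances and confirmation never exceeds presence", {
  per <- seq(2.2, 28, length.out = 40)
  set.seed(5)
  curves <- cbind(matrix(bumpCurve(7, per), 40, 6),
                  matrix(bumpCurve(25, per), 40, 6)) +
    matrix(rnorm(40 * 12, sd = 1e-3), 40)
  owners <- c(sprintf("s%02d", 1:6), sprintf("s%02d", c(1, 2, 3, 7, 8, 9)))
  rcs <- clusterMetaRhythms(curves, per * 24, subjectIds = owners,
                            maxK = 4, seed = 2)
  subjects <- data.frame(subjectId = sprintf("s%02d", 1:9),
                         gender = rep(c("F", "M", "F"), 3))
  pv <- prevalenceTable(rcs, subjects)
  expect_identical(dim(pv$counts), c(9L, 2L))
  expect_identical(sum(pv$counts), 12L)
  # s01 has one curve in each family; s09 only in the 25-d family
  expect_equal(unname(rowSums(pv$counts > 0)[c("s01", "s09")]), c(2, 1))
  expect_equal(pv$summary$nPresent, c(6, 6))
  # confirmation: give s01 a significant cluster covering the 25-d family
  g <- jidGrid(nSteps = 4L)
  pg <- periodGrid(voicesPerOctave = 32, periodMin = 36, periodMax = 36 * 2^5)
  ph <- periods(pg)
  lab <- matrix(0L, length(ph), 16)
  rows25 <- which(ph / 24 >= rcs@rangeMin[2] & ph / 24 <= rcs@rangeMax[2])
  lab[rows25, 1:2] <- 1L
  cs <- new("ClusterSet", labels = lab, sizes = length(rows25) * 2,
            significant = TRUE, fwThreshold = 3, nullMaxSizes = 1,
            minSize = 5, alpha = 0.05, grid = g, periodGrid = pg)
  pv2 <- prevalenceTable(rcs, subjects, clusterSets = list(s01 = cs))
  expect_true(all(pv2$confirmed <= (pv2$counts > 0)))
  expect_identical(sum(pv2$confirmed["s01", ]), 1L)
  expect_identical(sum(pv2$confirmed[-1, ]), 0L)
})
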