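# Block bootstrap, aperiodic adjustment, pointwise and cluster inference.

mkJid <- function(D, n = 4L, seed = 1) {
  set.seed(seed)
  dens <- array(rexp(n * n * D), dim = c(n, n, D))
  new("HourlyJID", grid = jidGrid(nSteps = n), hours = seq_len(D) - 1,
      density = dens, valid = rep(TRUE, D), droppedPairs = 0)
}

test_that("block resampling preserves length and the one-block identity", {
  set.seed(3)
  expect_identical(blockResampleIndices(24, 24), 1:24)   # D = 24: only block
  idx <- blockResampleIndices(100, 24)
  expect_length(idx, 100)
  expect_true(all(idx >= 1 & idx <= 96))
  # aligned starts land on day boundaries; moving starts need not
  expect_true(all((idx[seq(1, 100, 24)] - 1) %% 24 == 0))
  set.seed(3)
  mv <- replicate(20, blockResampleIndices(100, 24, style = "moving")[1])
  expect_true(any((mv - 1) %% 24 != 0))
  expect_error(blockResampleIndices(10, 24), "shorter than one block")
})

test_that("bootstrap means converge to the series mean", {
  jid <- mkJid(240)
  X <- densityMatrix(jid)
  set.seed(5)
  m <- rowMeans(replicate(500, colMeans(X[blockResampleIndices(240, 24), ])))
  expect_lt(max(abs(m / colMeans(X) - 1)), 0.05)
  # jointly shuffled: all bins share the block indices
  bb <- blockBootstrapJID(jid, seed = 9)
  expect_identical(dim(densityArray(bb)), dim(densityArray(jid)))
  set.seed(9)
  idx <- blockResampleIndices(240, 24)
  expect_equal(densityArray(bb), densityArray(jid)[, , idx], tolerance = 0)
})

test_that("aperiodic adjustment is exact, linear, and centers the null", {
  jid <- mkJid(24 * 30)
  pg <- periodGrid(voicesPerOctave = 3, periodMin = 36, periodMax = 24 * 8)
  raw <- jidPeriodograms(jid, pg)
  ens <- bootstrapPeriodograms(jid, pg, nBoot = 60, seed = 2)
  adj <- aperiodicAdjust(raw, ens)
  expect_equal(powerMatrix(adj), powerMatrix(raw) - ensembleMean(ens),
               tolerance = 1e-12)
  # real == ensemble mean -> adjusted == 0
  rawMean <- new("PeriodogramTensor", grid = raw@grid, periodGrid = pg,
                 power = ensembleMean(ens), kind = "raw")
  expect_true(all(abs(powerMatrix(aperiodicAdjust(rawMean, ens))) < 1e-12))
  # linearity: scaling real and ensemble scales the adjustment
  ens2 <- ens; ens2@power <- 2 * ens@power
  raw2 <- raw; raw2@power <- 2 * raw@power
  expect_equal(powerMatrix(aperiodicAdjust(raw2, ens2)),
               2 * powerMatrix(adj), tolerance = 1e-12)
  # white-noise subject: adjusted values center on 0
  pm <- powerMatrix(adj)
  expect_lt(abs(mean(pm)), 2 * sd(pm) / sqrt(4))   # grand mean ~ 0
  expect_error(aperiodicAdjust(adj, ens), "raw")
})

test_that("pointwise mask calibrates against the null and handles edges", {
  jid <- mkJid(24 * 30, seed = 11)
  pg <- periodGrid(voicesPerOctave = 3, periodMin = 36, periodMax = 24 * 8)
  ens <- bootstrapPeriodograms(jid, pg, nBoot = 100, seed = 4)
  # a member of the ensemble itself is masked at ~ alpha
  rates <- vapply(seq(1, 100, by = 7), function(b) {
    fake <- new("PeriodogramTensor", grid = jid@grid, periodGrid = pg,
                power = ens@power[, , b], kind = "raw")
    mean(pointwiseMask(fake, ens, alpha = 0.05))
  }, numeric(1))
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.09)
  # an extreme cell is always flagged
  raw <- jidPeriodograms(jid, pg)
  hot <- raw; hot@power[3, 5] <- 1e6
  expect_true(pointwiseMask(hot, ens)[3, 5])
  # alpha = 1 flags every usable cell
  expect_true(all(pointwiseMask(raw, ens, alpha = 1)))
  small <- ens; small@power <- ens@power[, , 1:20, drop = FALSE]
  expect_error(pointwiseMask(raw, small), "at least 40")
})

test_that("component labeling matches the flood-fill oracle", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (rep in 1:60) {
    arr <- array(runif(8 * 8 * 6) < runif(1, 0.05, 0.5), dim = c(8, 8, 6))
    lab <- multidien:::.labelArray(arr)
    oracle <- floodFillOracle(arr)
    expect_identical(sort(tabulate(lab)[tabulate(lab) > 0]),
                     sort(oracle$sizes))
    # identical partition: the two labelings are bijective relabelings
    cells <- which(arr)
    om <- oracle$membership
    pm <- lab[cells]
    expect_true(all(tapply(om, pm, function(v) length(unique(v))) == 1))
    expect_true(all(tapply(pm, om, function(v) length(unique(v))) == 1))
  }
})

test_that("cluster correction keeps a planted slab and obeys the 5-bin rule", {
  # planted 10 x 10 x 5 slab on a 5% noise background, brute-force oracle null
  set.seed(8)
  n <- 20L; Tn <- 12L
  g <- jidGrid(nSteps = n)
  pg <- periodGrid(voicesPerOctave = 2, periodMin = 36, periodMax = 36 * 2^6)
  stopifnot(length(periods(pg)) == Tn)
  nBoot <- 60
  ensP <- array(rexp(Tn * n * n * nBoot), dim = c(Tn, n * n, nBoot))
  ens <- new("BootstrapEnsemble", power = ensP, grid = g, periodGrid = pg,
             blockHours = 24, seed = 1)
  realP <- matrix(rexp(Tn * n * n), Tn, n * n)
  slabBins <- as.vector(outer(3:12, (5:14 - 1) * n, "+"))
  realP[4:8, slabBins] <- 10    # far outside the null
  real <- new("PeriodogramTensor", grid = g, periodGrid = pg,
              power = realP, kind = "raw")
  cs <- clusterCorrect(real, ens, alpha = 0.05, minSize = 5)
  expect_s4_class(cs, "ClusterSet")
  expect_true(any(isSignificant(cs)))
  big <- which.max(clusterSizes(cs))
  expect_gte(clusterSizes(cs)[big], 500)   # the slab
  expect_true(isSignificant(cs)[big])
  # the slab's period extent is recovered (chance-adjacent noise cells may
  # widen it by a period on either side)
  ext <- range(match(clusterPeriods(cs, big), periods(pg)))
  expect_lte(ext[1], 4L); expect_gte(ext[1], 3L)
  expect_gte(ext[2], 8L); expect_lte(ext[2], 9L)
  # 4 contiguous significant bins never form a retained cluster
  m <- matrix(FALSE, Tn, n * n)
  m[1, c(1, 2, n + 1, n + 2)] <- TRUE   # 2x2 patch, size 4 < 5
  lab <- multidien:::.retainClusters(multidien:::.labelMask(m, n), 5)
  expect_length(lab$sizes, 0)
  # empty mask -> empty ClusterSet path
  lab0 <- multidien:::.labelMask(matrix(FALSE, Tn, n * n), n)
  expect_identical(sum(lab0$labels), 0L)
})
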