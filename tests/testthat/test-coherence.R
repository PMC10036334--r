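# Pairwise wavelet phase coherence.

pgCoh <- periodGrid(voicesPerOctave = 8, periodMin = 24, periodMax = 32 * 24)

test_that("self-coherence is ~1 and coherence is symmetric", {
  set.seed(1)
  n <- 120 * 24
  x <- sin(2 * pi * seq_len(n) / (25 * 24)) + rnorm(n, sd = 0.5)
  y <- cos(2 * pi * seq_len(n) / (25 * 24)) + rnorm(n, sd = 0.5)
  band <- c(20, 30)
  expect_gte(pairBandCoherence(x, x, band, pgCoh), 0.99)
  cxy <- pairBandCoherence(x, y, band, pgCoh)
  cyx <- pairBandCoherence(y, x, band, pgCoh)
  expect_equal(cxy, cyx, tolerance = 1e-10)
  expect_true(cxy >= 0 && cxy <= 1)
})

test_that("short overlap and empty bands are rejected", {
  x <- rnorm(500)
  expect_error(pairBandCoherence(x, x, c(20, 30), pgCoh),
               "twice the band")
  expect_error(pairBandCoherence(x, x, c(100, 200), pgCoh),
               "no periods")
  expect_error(coherenceSignificance(rnorm(3000), rnorm(3000), c(1.5, 2),
                                     pgCoh, nBoot = 10),
               "at least 40")
})

test_that("phase-locked common signals are significant; independent noise is not", {
  set.seed(4)
  n <- 150 * 24
  common <- sin(2 * pi * seq_len(n) / (25 * 24))
  a <- common + rnorm(n, sd = 1)
  b <- common + rnorm(n, sd = 1)
  cs <- coherenceSignificance(a, b, c(23, 27), pgCoh, nBoot = 60, seed = 2)
  expect_true(cs$significant)
  expect_gt(cs$coherence, cs$threshold)
  # independent pair: typically below threshold
  set.seed(5)
  hits <- vapply(1:6, function(i) {
    u <- rnorm(n); v <- rnorm(n)
    coherenceSignificance(u, v, c(23, 27), pgCoh, nBoot = 40,
                          seed = 100 + i)$significant
  }, logical(1))
  expect_lte(sum(hits), 2)
})

test_that("the reference bin comes from the largest in-band cluster", {
  g <- jidGrid(nSteps = 5L)
  pg <- periodGrid(voicesPerOctave = 4, periodMin = 36, periodMax = 36 * 2^6)
  ph <- periods(pg)
  Tn <- length(ph)
  lab <- matrix(0L, Tn, 25)
  inBand <- which(ph / 24 >= 20 & ph / 24 <= 30)
  lab[inBand, 1:4] <- 1L                  # 4-bin-wide cluster (largest)
  lab[inBand[1:2], 10:11] <- 2L           # smaller cluster
  pw <- matrix(0, Tn, 25)
  pw[inBand[1], 10] <- 100                # global max sits in the SMALL cluster
  pw[inBand[2], 3] <- 5                   # max within the large cluster
  cs <- new("ClusterSet", labels = lab,
            sizes = c(sum(lab == 1L), sum(lab == 2L)),
            significant = c(TRUE, TRUE), fwThreshold = 1, nullMaxSizes = 0,
            minSize = 5, alpha = 0.05, grid = g, periodGrid = pg)
  adj <- new("PeriodogramTensor", grid = g, periodGrid = pg, power = pw,
             kind = "adjusted")
  rb <- selectReferenceBin(cs, adj, c(20, 30))
  expect_identical(rb, list(row = 3L, col = 1L))   # bin 3 of the big cluster
  # single one-bin cluster: that bin
  lab2 <- matrix(0L, Tn, 25); lab2[inBand[1], 7] <- 1L
  cs2 <- new("ClusterSet", labels = lab2, sizes = 1, significant = TRUE,
             fwThreshold = 0, nullMaxSizes = 0, minSize = 1, alpha = 0.05,
             grid = g, periodGrid = pg)
  expect_identical(selectReferenceBin(cs2, adj, c(20, 30)),
                   list(row = 2L, col = 2L))
  # no significant cluster in band -> NULL
  expect_null(selectReferenceBin(cs2, adj, c(2, 3)))
})

test_that("cohort coherence enumerates pairs and splits by gender class", {
  set.seed(11)
  n <- 4L
  D <- 70 * 24
  mk <- function(seed) {
    set.seed(seed)
    dens <- array(rexp(n * n * D), dim = c(n, n, D))
    new("HourlyJID", grid = jidGrid(nSteps = n), hours = seq_len(D) - 1,
        density = dens, valid = rep(TRUE, D), droppedPairs = 0)
  }
  jids <- list(a = mk(1), b = mk(2), c = mk(3))
  rb <- list(a = list(row = 1L, col = 1L), b = list(row = 2L, col = 2L),
             c = list(row = 1L, col = 2L))
  pgS <- periodGrid(voicesPerOctave = 6, periodMin = 24, periodMax = 20 * 24)
  cr <- cohortCoherence(jids, c(10, 14), pgS, refBins = rb,
                        genders = c(a = "F", b = "M", c = "F"),
                        nBoot = 40, seed = 5)
  expect_s4_class(cr, "CoherenceResult")
  expect_identical(nrow(cr@pairs), 3L)   # 3 subjects -> 3 unordered pairs
  expect_setequal(cr@pairs$pairClass, c("FM", "FF"))
  expect_true(all(cr@pairs$coherence >= 0 & cr@pairs$coherence <= 1))
  expect_equal(sum(cr@rates$nPairs), 3, ignore_attr = TRUE)
})
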