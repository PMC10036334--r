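# Joint-interval distribution construction.

test_that("the default grid discretizes [1.5, 5] log10(ms) into 2500 bins", {
  g <- jidGrid()
  bc <- binCenters(g)
  expect_length(bc, 50)
  expect_identical(g@nSteps^2, 2500)
  expect_true(all(diff(bc) > 0))
  expect_equal(max(abs(diff(bc) - 0.07)), 0, tolerance = 1e-12)
  expect_equal(bc[1], 1.5 + 0.07 / 2)
  expect_equal(bc[50], 5.0 - 0.07 / 2)
})

test_that("sessionize partitions touches by enclosing on/off spans", {
  expect_identical(sessionize(exampleStream())[[1]],
                   events(exampleStream())$timestampMs[2:7])
  # on@0, touches at 1000/2000/4000, off@5000 -> one session, ITIs 1000, 2000
  ev <- data.frame(
    timestampMs = c(0, 1000, 2000, 4000, 5000),
    type = c("screen_on", "touch", "touch", "touch", "screen_off"))
  st <- new("TouchEventStream", subjectId = "x", events = ev,
            age = NULL, gender = NULL)
  ss <- sessionize(st)
  expect_length(ss, 1)
  expect_identical(diff(ss[[1]]), c(1000, 2000))
  # a stream with no touches
  ev2 <- ev[c(1, 5), ]
  st2 <- new("TouchEventStream", subjectId = "x", events = ev2,
             age = NULL, gender = NULL)
  expect_identical(sessionize(st2), list())
})

test_that("pairs never span session boundaries and land in onset hours", {
  # two sessions of 3 touches each -> 1 pair per session, none across the gap
  s1 <- c(1000, 2000, 4000)
  s2 <- 3600e3 + c(0, 500, 1500)   # second session in hour 1
  st <- streamFromSessions(list(s1, s2))
  hp <- hourlyPairs(sessionize(st))
  expect_identical(nrow(hp$pairs), 2L)
  expect_identical(sort(unique(hp$pairs$hour)), c(0, 1))
  # log10 arithmetic: ITIs [1000, 2000, 500] -> pairs (3, 3.301), (3.301, 2.699)
  st3 <- streamFromSessions(list(c(0, 1000, 3000, 3500)))
  p3 <- hourlyPairs(sessionize(st3))$pairs
  expect_equal(p3$x, c(3, log10(2000)), tolerance = 1e-12)
  expect_equal(p3$y, c(log10(2000), log10(500)), tolerance = 1e-12)
  # single-ITI session contributes no pairs
  expect_identical(
    nrow(hourlyPairs(list(c(0, 1000)))$pairs), 0L)
  # duplicate timestamps are dropped and counted
  hpd <- hourlyPairs(list(c(0, 1000, 1000, 2000)))
  expect_identical(hpd$dropped, 1L)
})

test_that("KDE matches brute-force kernel evaluation and leaks mass", {
  g <- jidGrid(nSteps = 25L)
  bc <- binCenters(g)
  # single pair: argmax at the nearest bin center; brute-force agreement
  d <- estimateJID(3.02, 3.33, g)
  brute <- outer(bc, bc, function(a, b)
    dnorm(a, 3.02, 0.1) * dnorm(b, 3.33, 0.1))
  expect_equal(d, brute, tolerance = 1e-12)
  am <- arrayInd(which.max(d), dim(d))
  expect_identical(am[1], which.min(abs(bc - 3.02)))
  expect_identical(am[2], which.min(abs(bc - 3.33)))
  # duplicated sample set leaves the density unchanged
  d2 <- estimateJID(c(3.02, 3.02), c(3.33, 3.33), g)
  expect_equal(d, d2, tolerance = 1e-12)
  # in-window mass ~1; out-of-window pair leaks most of its mass
  step <- diff(bc)[1]
  expect_lt(abs(sum(d) * step^2 - 1), 0.02)
  dOut <- estimateJID(5.5, 5.5, g)
  expect_lt(sum(dOut) * step^2, 0.01)
})

test_that("the JID tensor covers the calendar, flags gaps, conserves mass", {
  cfg <- subjectConfig(durationDays = 10, seed = 21,
                       gaps = data.frame(startDay = 5, lengthDays = 1))
  st <- generateSubject(cfg)
  jid <- buildJID(st, jidGrid(nSteps = 20L))
  D <- length(hourAxis(jid))
  expect_true(D >= 200 && D <= 240)
  expect_true(all(diff(hourAxis(jid)) == 1))
  # interior gap hours invalid and all-zero (a session straddling the gap
  # start may spill pairs into the first gap hour)
  org <- multidien:::.ORIGIN_MS / 3600e3
  gapHours <- hourAxis(jid) > org + 5 * 24 & hourAxis(jid) < org + 6 * 24
  expect_true(any(gapHours))
  expect_false(any(validHours(jid)[gapHours]))
  expect_true(all(densityArray(jid)[, , gapHours] == 0))
  # conservation: hours with interior pairs integrate to ~1; a few hours
  # whose only pairs sit near/past the truncation bound may leak more
  step <- diff(binCenters(jid@grid))[1]
  mass <- colSums(matrix(densityArray(jid), 400, D)) * step^2
  vm <- mass[validHours(jid)]
  expect_true(all(vm <= 1.01))
  expect_gt(median(vm), 0.9)
  expect_gt(mean(vm > 0.85), 0.9)
  expect_true(all(mass[!validHours(jid)] == 0))
})

test_that("translating timestamps by whole hours translates the tensor", {
  st <- generateSubject(subjectConfig(durationDays = 3, seed = 8))
  ev <- events(st)
  ev$timestampMs <- ev$timestampMs + 5 * 3600e3
  st2 <- new("TouchEventStream", subjectId = "shift", events = ev,
             age = NULL, gender = NULL)
  g <- jidGrid(nSteps = 15L)
  a <- buildJID(st, g)
  b <- buildJID(st2, g)
  expect_equal(hourAxis(b), hourAxis(a) + 5)
  expect_equal(densityArray(b), densityArray(a), tolerance = 1e-12)
})

test_that("streams without any interval pair are rejected", {
  st <- streamFromSessions(list(c(0, 1000)))
  expect_error(buildJID(st, jidGrid(nSteps = 10L)), "no interval pairs")
})

test_that("more fast pairs put more mass in the low-log10 quadrant", {
  mk <- function(w0, seed) {
    st <- generateSubject(subjectConfig(durationDays = 5, fastWeight = w0,
                                        seed = seed))
    jid <- buildJID(st, jidGrid(nSteps = 20L))
    d <- densityArray(jid)[, , validHours(jid), drop = FALSE]
    m <- apply(d, c(1, 2), mean)
    sum(m[1:10, 1:10]) / sum(m)
  }
  expect_gt(mk(0.8, 4), mk(0.3, 4))
})
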