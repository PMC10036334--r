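# Synthetic touchscreen event streams with known injected rhythms.
#
# The generator emulates the structure the analysis consumes: screen-on/off
# sessions started at an hourly (circadian) rate, heavy-tailed inter-touch
# intervals from a two-component log-normal mixture in log10(ms), multi-day
# sinusoidal modulation of the fast-component weight (or the session rate),
# and day-scale recording gaps that are honest missing data.

# Synthetic calendar origin: a midnight, so hour 0 is a clock midnight.
.ORIGIN_DAY <- 18500
.ORIGIN_MS <- .ORIGIN_DAY * 86400e3

#' Default circadian session-rate profile
#'
#' Expected sessions started per clock hour: near-silent at night, ramping
#' through the morning, sustained through the day and evening. Sums to ~40
#' sessions/day which, at ~20 touches per session, yields ~800 touches/day.
#'
#' @return numeric vector of length 24.
#' @export
defaultSessionProfile <- function() {
  c(0.2, 0.1, 0.1, 0.1, 0.1, 0.2, 0.5, 1.5, 2.5, 3.0, 3.0, 3.0,
    3.0, 2.5, 2.5, 2.5, 2.5, 2.5, 2.5, 3.0, 3.0, 2.5, 1.5, 0.5)
}

#' Construct a synthetic-subject configuration
#'
#' Defaults are fixed study conditions, not tuning knobs: the mixture places
#' the fast component at 10^2.5 ms and the slow at 10^4.3 ms so that with
#' baseline fast weight 0.6 about 1% of intervals exceed 10^5 ms (the upper
#' truncation bound of the JID window is the empirical 99th percentile).
#'
#' @param durationDays days of recording.
#' @param sessionRateProfile 24-vector, expected sessions per clock hour.
#' @param fastMean,fastSd,slowMean,slowSd log10(ms) mixture parameters.
#' @param fastWeight baseline weight of the fast component, in \[0, 1\].
#' @param rhythms data.frame (periodDays, amplitude, phase, target) of
#'   injected multi-day sinusoids; \code{target} is \code{"weight"} (the
#'   fast mixture weight w(t) = w0 + a sin(2 pi t / period + phase)) or
#'   \code{"rate"} (multiplies the session rate by 1 + a sin(...)).
#' @param gaps data.frame (startDay, lengthDays) of recording gaps.
#' @param seed integer RNG seed.
#' @return a [SubjectConfig-class].
#' @examples
#' cfg <- subjectConfig(durationDays = 30, seed = 1)
#' @export
subjectConfig <- function(durationDays = 90,
                          sessionRateProfile = defaultSessionProfile(),
                          fastMean = 2.5, fastSd = 0.35,
                          slowMean = 4.3, slowSd = 0.36,
                          fastWeight = 0.6,
                          rhythms = noRhythms(),
                          gaps = noGaps(),
                          seed = 1L) {
  new("SubjectConfig",
      durationDays = durationDays,
      sessionRateProfile = sessionRateProfile,
      fastMean = fastMean, fastSd = fastSd,
      slowMean = slowMean, slowSd = slowSd,
      fastWeight = fastWeight,
      rhythms = rhythms, gaps = gaps, seed = as.numeric(seed))
}

#' Empty rhythm table
#' @return zero-row data.frame with the rhythm columns.
#' @export
noRhythms <- function() {
  data.frame(periodDays = numeric(0), amplitude = numeric(0),
             phase = numeric(0), target = character(0))
}

#' Rhythm table helper
#' @param periodDays rhythm period in days (> 2).
#' @param amplitude sinusoid amplitude (weight units or relative rate).
#' @param phase phase in radians.
#' @param target \code{"weight"} or \code{"rate"}.
#' @return one-row-per-rhythm data.frame.
#' @export
rhythmSpec <- function(periodDays, amplitude, phase = 0, target = "weight") {
  data.frame(periodDays = periodDays, amplitude = amplitude,
             phase = phase, target = target)
}

#' Empty gap table
#' @return zero-row data.frame with the gap columns.
#' @export
noGaps <- function() {
  data.frame(startDay = numeric(0), lengthDays = numeric(0))
}

# Sum of injected sinusoids for one target, evaluated at t (days).
.rhythmSignal <- function(rhythms, target, tDays) {
  rh <- rhythms[rhythms$target == target, , drop = FALSE]
  s <- numeric(length(tDays))
  for (i in seq_len(nrow(rh)))
    s <- s + rh$amplitude[i] *
      sin(2 * pi * tDays / rh$periodDays[i] + rh$phase[i])
  s
}

#' Generate one synthetic subject's event stream
#'
#' Sessions start as an inhomogeneous Poisson process at the configured
#' hourly rate; each session draws a geometric touch count (mean 20) and
#' its inter-touch intervals from the (possibly rhythm-modulated) log-normal
#' mixture. A screen_on event opens each session and a screen_off is placed
#' 1 s after the last touch; overlapping sessions are dropped in favour of
#' the earlier one. Gap days carry no events of any kind. Output is
#' deterministic given the config (including its seed).
#'
#' @param config a [SubjectConfig-class].
#' @param subjectId character id for the stream.
#' @param age,gender optional metadata carried into the stream.
#' @return a [TouchEventStream-class].
#' @examples
#' st <- generateSubject(subjectConfig(durationDays = 5, seed = 7))
#' @export
generateSubject <- function(config, subjectId = "synthetic-1",
                            age = NULL, gender = NULL) {
  validObject(config)
  set.seed(config@seed)
  nHours <- as.integer(round(config@durationDays * 24))
  hour <- seq_len(nHours) - 1L
  rate <- config@sessionRateProfile[hour %% 24L + 1L]

  # rate-targeted rhythms modulate the expected session count
  mod <- .rhythmSignal(config@rhythms, "rate", hour / 24)
  rate <- pmax(rate * (1 + mod), 0)

  # recording gaps: silence, not zeros
  inGap <- rep(FALSE, nHours)
  for (i in seq_len(nrow(config@gaps))) {
    g0 <- config@gaps$startDay[i] * 24
    g1 <- g0 + config@gaps$lengthDays[i] * 24
    inGap[hour >= g0 & hour < g1] <- TRUE
  }
  rate[inGap] <- 0

  nSess <- stats::rpois(nHours, rate)
  total <- sum(nSess)
  if (total == 0L) {
    return(new("TouchEventStream", subjectId = subjectId,
               events = .emptyEvents(), age = age, gender = gender))
  }
  startHour <- rep(hour, nSess)
  starts <- sort((startHour + stats::runif(total)) * 3600e3)

  nTouch <- 1L + stats::rgeom(total, 1 / 20)
  nIti <- nTouch - 1L

  # fast-component weight at each session's start
  w <- config@fastWeight +
    .rhythmSignal(config@rhythms, "weight", starts / 86400e3)
  w <- pmin(pmax(w, 0), 1)

  fast <- stats::runif(sum(nIti)) < rep(w, nIti)
  logIti <- stats::rnorm(sum(nIti),
                         mean = ifelse(fast, config@fastMean, config@slowMean),
                         sd = ifelse(fast, config@fastSd, config@slowSd))
  iti <- 10^logIti

  # per-session cumulative interval offsets
  cs0 <- c(0, cumsum(iti))
  endIdx <- cumsum(nIti)                            # cumulative ITI count
  before <- cs0[endIdx - nIti + 1]                  # total before each session
  offsets <- cs0[-1] - rep(before, nIti)            # within-session cumsum
  sessTotal <- cs0[endIdx + 1] - before

  sessEnd <- starts + sessTotal + 1000             # screen_off 1 s after last

  # drop sessions that would overlap the previous one (earlier wins)
  keep <- logical(total)
  lastEnd <- -Inf
  for (i in seq_len(total)) {
    if (starts[i] - 50 > lastEnd) {   # 50 ms margin: screen_on precedes first touch
      keep[i] <- TRUE
      lastEnd <- sessEnd[i]
    }
  }
  keepIti <- rep(keep, nIti)

  firstTouch <- starts[keep]
  laterTouch <- rep(starts, nIti)[keepIti] + offsets[keepIti]
  touches <- c(firstTouch, laterTouch)

  ts <- c(starts[keep] - 50, touches, sessEnd[keep])
  type <- c(rep("screen_on", sum(keep)),
            rep("touch", length(touches)),
            rep("screen_off", sum(keep)))
  o <- order(ts, method = "radix")
  ev <- data.frame(timestampMs = round(.ORIGIN_MS + ts[o]),
                   type = type[o], stringsAsFactors = FALSE)
  new("TouchEventStream", subjectId = subjectId, events = ev,
      age = age, gender = gender)
}

.emptyEvents <- function() {
  data.frame(timestampMs = numeric(0), type = character(0),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' All subjects share the base configuration; rhythm phases are either
#' identical across subjects (\code{"shared"}) or drawn i.i.d. uniform on
#' \[0, 2 pi) per subject (\code{"independent"}). Per-subject seeds are
#' derived from \code{seed} so each stream is individually reproducible.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param baseConfig a [SubjectConfig-class] shared by the cohort.
#' @param phaseMode \code{"shared"} or \code{"independent"}.
#' @param seed integer master seed for the cohort.
#' @param genders character vector recycled over subjects.
#' @param ages numeric vector recycled over subjects.
#' @return list of [TouchEventStream-class], names = subject ids.
#' @export
generateCohort <- function(nSubjects, baseConfig,
                           phaseMode = c("independent", "shared"),
                           seed = 1L,
                           genders = c("F", "M"),
                           ages = seq(20, 75, length.out = nSubjects)) {
  stopifnot(nSubjects >= 2)
  phaseMode <- match.arg(phaseMode)
  set.seed(seed)
  subSeeds <- sample.int(2147483600L, nSubjects)
  nr <- nrow(baseConfig@rhythms)
  phases <- matrix(rep(baseConfig@rhythms$phase, each = nSubjects),
                   nSubjects, nr)
  if (phaseMode == "independent" && nr > 0)
    phases <- matrix(stats::runif(nSubjects * nr, 0, 2 * pi), nSubjects, nr)
  genders <- rep_len(genders, nSubjects)
  ages <- rep_len(ages, nSubjects)
  out <- vector("list", nSubjects)
  for (i in seq_len(nSubjects)) {
    cfg <- baseConfig
    if (nr > 0) cfg@rhythms$phase <- phases[i, ]
    cfg@seed <- as.numeric(subSeeds[i])
    id <- sprintf("synthetic-%03d", i)
    out[[i]] <- generateSubject(cfg, subjectId = id,
                                age = ages[i], gender = genders[i])
  }
  names(out) <- vapply(out, subjectId, character(1))
  attr(out, "phases") <- phases   # subjects x rhythms, for recovery checks
  out
}

#' Minimal six-touch demonstration stream
#'
#' One screen-on session containing exactly six touch events, yielding five
#' inter-touch intervals and four consecutive-interval pairs — the smallest
#' stream on which the joint-interval machinery is fully exercised.
#'
#' @return a [TouchEventStream-class].
#' @examples
#' st <- exampleStream()
#' sum(events(st)$type == "touch")  # 6
#' @export
exampleStream <- function() {
  touch <- .ORIGIN_MS + c(100, 1100, 1500, 3100, 3500, 5100)
  ev <- data.frame(
    timestampMs = c(.ORIGIN_MS, touch, .ORIGIN_MS + 6100),
    type = c("screen_on", rep("touch", 6), "screen_off"),
    stringsAsFactors = FALSE)
  new("TouchEventStream", subjectId = "demo-6", events = ev,
      age = NULL, gender = NULL)
}
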