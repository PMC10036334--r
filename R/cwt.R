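# Continuous-wavelet periodograms.
#
# Analytic Morlet wavelet (center frequency omega0 = 6), implemented in the
# frequency domain: the transform at scale s is the inverse FFT of the
# series spectrum multiplied by sqrt(2 pi s / dt) * pi^(-1/4) *
# exp(-(s w - omega0)^2 / 2) on positive frequencies. The periodogram power
# at a period is P = sqrt(mean |S|), the temporal mean restricted to
# samples outside the cone of influence (e-folding time sqrt(2) s).

.MORLET_OMEGA0 <- 6

# Fourier factor: period / scale for the Morlet wavelet.
.fourierFactor <- function(omega0 = .MORLET_OMEGA0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Construct the geometric period grid of the wavelet filterbank
#'
#' Periods are spaced geometrically at \code{voicesPerOctave} voices per
#' octave: p_j = periodMin * 2^(j/V) for j = 1..N with
#' N = floor(V log2(periodMax / periodMin)). The defaults (1-hour sampling,
#' 40 voices, 2 hours to 80 days) give 396 periods.
#'
#' @param samplingPeriod hours per sample.
#' @param voicesPerOctave voices per octave (>= 1).
#' @param periodMin,periodMax period limits in hours (exclusive lower,
#'   inclusive upper when it falls on a voice).
#' @return a [PeriodGrid-class].
#' @examples
#' length(periods(periodGrid()))  # 396
#' @export
periodGrid <- function(samplingPeriod = 1, voicesPerOctave = 40,
                       periodMin = 2, periodMax = 80 * 24) {
  if (periodMin <= 0 || periodMax <= 0 || periodMin >= periodMax)
    stop("need 0 < periodMin < periodMax")
  if (voicesPerOctave < 1) stop("voicesPerOctave must be >= 1")
  V <- voicesPerOctave
  N <- floor(V * log2(periodMax / periodMin) + 1e-9)
  p <- periodMin * 2^(seq_len(N) / V)
  new("PeriodGrid", samplingPeriod = samplingPeriod,
      voicesPerOctave = V, periodMin = periodMin, periodMax = periodMax,
      periods = p)
}

# Npad x T matrix of analytic Morlet kernels (real-valued on the FFT
# frequency axis, zero on negative frequencies and at DC).
.morletKernels <- function(Npad, dt, periodsH, omega0 = .MORLET_OMEGA0) {
  k <- seq_len(Npad) - 1
  omega <- 2 * pi * ifelse(k <= Npad / 2, k, k - Npad) / (Npad * dt)
  scales <- periodsH / .fourierFactor(omega0)
  W <- matrix(0, Npad, length(scales))
  pos <- omega > 0
  for (j in seq_along(scales)) {
    s <- scales[j]
    W[pos, j] <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-((s * omega[pos] - omega0)^2) / 2)
  }
  W
}

# 0-based inclusive out-of-COI sample bounds per period; lo > hi when the
# cone of influence leaves no samples at that period.
.coiBounds <- function(N, dt, periodsH, omega0 = .MORLET_OMEGA0) {
  scales <- periodsH / .fourierFactor(omega0)
  efold <- ceiling(sqrt(2) * scales / dt)
  list(lo = as.integer(efold), hi = as.integer(N - 1 - efold))
}

#' Wavelet periodogram power of hourly series (batched)
#'
#' Applies the Morlet periodogram independently to each column of
#' \code{X}. Series are zero-padded to a fast FFT length; periods whose
#' cone of influence leaves no samples return NaN.
#'
#' @param X numeric matrix D x B of hourly series (or a vector, treated as
#'   one column).
#' @param pgrid a [PeriodGrid-class].
#' @return numeric matrix T x B of power values, rownames = periods (h).
#' @examples
#' x <- sin(2 * pi * seq_len(2000) / 170)
#' p <- cwtPower(x, periodGrid(voicesPerOctave = 8, periodMin = 24,
#'                             periodMax = 480))
#' @export
cwtPower <- function(X, pgrid) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  D <- nrow(X)
  if (D < 2L) stop("need at least 2 samples")
  if (!all(is.finite(X))) stop("series must be finite")
  dt <- pgrid@samplingPeriod
  ph <- pgrid@periods
  cb <- .coiBounds(D, dt, ph)
  if (all(cb$lo > cb$hi)) {
    stop(sprintf(
      "series too short for every period in the grid; maximum usable period is %.1f h",
      (D * dt / 2 - dt) / sqrt(2) * .fourierFactor()))
  }
  Npad <- stats::nextn(D, c(2, 3))
  # demean before zero-padding: zero-mean wavelets annihilate constants, and
  # demeaning avoids the spurious edge step a padded constant offset creates
  X <- sweep(X, 2, colMeans(X))
  Xp <- rbind(X, matrix(0, Npad - D, ncol(X)))
  F <- stats::mvfft(Xp)
  W <- .morletKernels(Npad, dt, ph)
  P <- cwt_power_impl(F, W, cb$lo, cb$hi)
  rownames(P) <- signif(ph, 8)
  P
}

#' Full wavelet coefficients of one hourly series
#'
#' Used by the coherence stage, which needs time-resolved coefficients for
#' smoothing, not just the time-averaged power.
#'
#' @param x numeric vector, hourly samples.
#' @param pgrid a [PeriodGrid-class].
#' @param select optional integer indices of periods to compute.
#' @return list: \code{coef}, complex matrix D x length(select);
#'   \code{coi}, logical matrix D x length(select), TRUE outside the cone
#'   of influence; \code{periods}, hours.
#' @export
cwtCoeffs <- function(x, pgrid, select = seq_along(pgrid@periods)) {
  D <- length(x)
  dt <- pgrid@samplingPeriod
  ph <- pgrid@periods[select]
  Npad <- stats::nextn(D, c(2, 3))
  fhat <- stats::fft(c(x - mean(x), rep(0, Npad - D)))
  W <- .morletKernels(Npad, dt, ph)
  cb <- .coiBounds(D, dt, ph)
  S <- matrix(0 + 0i, D, length(ph))
  coi <- matrix(FALSE, D, length(ph))
  for (j in seq_along(ph)) {
    S[, j] <- stats::fft(fhat * W[, j], inverse = TRUE)[seq_len(D)] / Npad
    if (cb$lo[j] <= cb$hi[j])
      coi[(cb$lo[j] + 1):(cb$hi[j] + 1), j] <- TRUE
  }
  list(coef = S, coi = coi, periods = ph)
}

#' Per-bin wavelet periodograms of an hourly JID
#'
#' Applies [cwtPower()] to every JID bin's hourly density series; there is
#' no coupling across bins. Invalid hours enter as zeros.
#'
#' @param jid an [HourlyJID-class].
#' @param pgrid a [PeriodGrid-class].
#' @return a [PeriodogramTensor-class] of kind \code{"raw"}.
#' @export
jidPeriodograms <- function(jid, pgrid) {
  P <- cwtPower(densityMatrix(jid), pgrid)
  new("PeriodogramTensor", grid = jid@grid, periodGrid = pgrid,
      power = P, kind = "raw")
}
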