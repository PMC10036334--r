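#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

# ---------------------------------------------------------------------------
# Synthetic generator configuration
# ---------------------------------------------------------------------------

#' Configuration of one synthetic subject
#'
#' Describes a synthetic smartphone user: how many days are recorded, the
#' expected number of screen-on sessions per clock hour, a two-component
#' log-normal mixture (in log10 milliseconds) for inter-touch intervals,
#' optional multi-day sinusoidal rhythms modulating either the fast-interval
#' mixture weight or the session rate, and recording gaps.
#'
#' @slot durationDays integer scalar, days of recording.
#' @slot sessionRateProfile numeric of length 24, expected sessions started
#'   per clock hour (hour 0 = midnight UTC).
#' @slot fastMean,fastSd,slowMean,slowSd numeric, log10(ms) parameters of the
#'   fast and slow interval mixture components.
#' @slot fastWeight numeric in \[0, 1\], baseline weight of the fast component.
#' @slot rhythms data.frame with columns \code{periodDays}, \code{amplitude},
#'   \code{phase}, \code{target} (\code{"weight"} or \code{"rate"}).
#' @slot gaps data.frame with columns \code{startDay}, \code{lengthDays}.
#' @slot seed integer RNG seed.
#'
#' @seealso [subjectConfig()] for the validated constructor.
#' @exportClass SubjectConfig
setClass("SubjectConfig",
  representation(
    durationDays = "numeric",
    sessionRateProfile = "numeric",
    fastMean = "numeric", fastSd = "numeric",
    slowMean = "numeric", slowSd = "numeric",
    fastWeight = "numeric",
    rhythms = "data.frame",
    gaps = "data.frame",
    seed = "numeric"
  )
)

setValidity("SubjectConfig", function(object) {
  msg <- character(0)
  if (length(object@durationDays) != 1L || object@durationDays <= 0)
    msg <- c(msg, "durationDays must be a positive scalar")
  if (length(object@sessionRateProfile) != 24L)
    msg <- c(msg, "sessionRateProfile must have exactly 24 entries")
  if (any(object@sessionRateProfile < 0))
    msg <- c(msg, "sessionRateProfile entries must be >= 0")
  if (object@fastWeight < 0 || object@fastWeight > 1)
    msg <- c(msg, "fastWeight must lie in [0, 1]")
  if (any(c(object@fastSd, object@slowSd) <= 0))
    msg <- c(msg, "mixture standard deviations must be positive")
  rh <- object@rhythms
  if (nrow(rh)) {
    need <- c("periodDays", "amplitude", "phase", "target")
    if (!all(need %in% names(rh))) {
      msg <- c(msg, "rhythms needs columns periodDays, amplitude, phase, target")
    } else {
      if (any(rh$periodDays <= 2))
        msg <- c(msg, "rhythm periods must exceed 2 days (multi-day rhythms)")
      if (!all(rh$target %in% c("weight", "rate")))
        msg <- c(msg, "rhythm target must be 'weight' or 'rate'")
      w0 <- object@fastWeight
      aw <- sum(rh$amplitude[rh$target == "weight"])
      if (nrow(rh) && any(rh$amplitude < 0))
        msg <- c(msg, "rhythm amplitudes must be >= 0")
      if (aw > min(w0, 1 - w0) + 1e-12)
        msg <- c(msg, sprintf(
          "total weight-rhythm amplitude %.3f pushes the fast weight out of [0, 1] (baseline %.3f); reduce amplitude",
          aw, w0))
      ar <- sum(rh$amplitude[rh$target == "rate"])
      if (ar > 1 + 1e-12)
        msg <- c(msg, "total rate-rhythm amplitude must be <= 1 (rate must stay >= 0)")
    }
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Event streams
# ---------------------------------------------------------------------------

#' One subject's touchscreen event stream
#'
#' An ordered table of touchscreen interaction events: touch timestamps plus
#' the screen "on"/"off" events that delimit usage sessions. Timestamps are
#' UTC milliseconds. Optional demographic metadata (age, gender) ride along
#' for population summaries.
#'
#' @slot subjectId character scalar.
#' @slot events data.frame with columns \code{timestampMs} (numeric, UTC ms)
#'   and \code{type} (one of \code{"touch"}, \code{"screen_on"},
#'   \code{"screen_off"}), ordered by timestamp.
#' @slot age numeric or NULL.
#' @slot gender character or NULL (free label, e.g. \code{"F"}/\code{"M"}).
#'
#' @exportClass TouchEventStream
setClass("TouchEventStream",
  representation(
    subjectId = "character",
    events = "data.frame",
    age = "numericOrNULL",
    gender = "characterOrNULL"
  )
)

setValidity("TouchEventStream", function(object) {
  ev <- object@events
  msg <- character(0)
  if (!all(c("timestampMs", "type") %in% names(ev)))
    return("events needs columns timestampMs, type")
  if (nrow(ev)) {
    if (!all(ev$type %in% c("touch", "screen_on", "screen_off")))
      msg <- c(msg, "event types must be touch/screen_on/screen_off")
    if (is.unsorted(ev$timestampMs))
      msg <- c(msg, "events must be ordered by timestamp")
    n_on <- sum(ev$type == "screen_on")
    n_off <- sum(ev$type == "screen_off")
    if (n_on != n_off)
      msg <- c(msg, "every screen_on needs a matching screen_off")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# JID grid and hourly JID tensor
# ---------------------------------------------------------------------------

#' Discretization grid of the joint-interval distribution
#'
#' The estimation window of consecutive inter-touch interval pairs, on
#' log10-millisecond axes. The default window is \[10^1.5, 10^5\] ms
#' (about 30 ms to 2 min) in 50 equal log10 steps per dimension, i.e. 2500
#' two-dimensional bins; densities are evaluated at bin centers.
#'
#' @slot axisMin,axisMax numeric, log10(ms) window bounds.
#' @slot nSteps integer, bins per dimension.
#' @slot binCenters numeric of length \code{nSteps}.
#'
#' @seealso [jidGrid()]
#' @exportClass JIDGrid
setClass("JIDGrid",
  representation(
    axisMin = "numeric", axisMax = "numeric",
    nSteps = "numeric", binCenters = "numeric"
  )
)

setValidity("JIDGrid", function(object) {
  msg <- character(0)
  if (object@axisMin >= object@axisMax) msg <- c(msg, "axisMin must be < axisMax")
  bc <- object@binCenters
  if (length(bc) != object@nSteps) msg <- c(msg, "binCenters length must equal nSteps")
  if (length(bc) > 1) {
    d <- diff(bc)
    if (any(d <= 0)) msg <- c(msg, "bin centers must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-9) msg <- c(msg, "bin centers must be equally spaced")
  }
  if (length(msg)) msg else TRUE
})

#' Hourly joint-interval distribution tensor
#'
#' Kernel density estimates of the joint distribution of consecutive
#' log10 inter-touch intervals, accumulated in consecutive one-hour bins.
#' Hours without interval pairs carry an all-zero density and are flagged
#' invalid; zeros (not interpolations) are what the wavelet stage sees, so
#' the hourly sampling grid stays regular.
#'
#' @slot grid a [JIDGrid-class].
#' @slot hours numeric, consecutive UTC epoch hours (ms-epoch / 3.6e6).
#' @slot density numeric array nSteps x nSteps x D; probability density over
#'   the log10 x log10 window.
#' @slot valid logical of length D, TRUE where the hour had >= 1 pair.
#' @slot droppedPairs numeric, count of non-positive intervals discarded.
#'
#' @seealso [buildJID()]
#' @exportClass HourlyJID
setClass("HourlyJID",
  representation(
    grid = "JIDGrid",
    hours = "numeric",
    density = "array",
    valid = "logical",
    droppedPairs = "numeric"
  )
)

setValidity("HourlyJID", function(object) {
  msg <- character(0)
  d <- dim(object@density)
  n <- object@grid@nSteps
  if (length(d) != 3L || d[1] != n || d[2] != n)
    msg <- c(msg, "density must be nSteps x nSteps x D")
  if (length(object@hours) != d[3]) msg <- c(msg, "hours length must equal D")
  if (length(object@valid) != d[3]) msg <- c(msg, "valid length must equal D")
  if (length(object@hours) > 1 && any(diff(object@hours) != 1))
    msg <- c(msg, "hours must be consecutive")
  if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Period grid and periodogram tensors
# ---------------------------------------------------------------------------

#' Geometric period grid of the wavelet filterbank
#'
#' Periods p_j = periodMin * 2^(j / voicesPerOctave), j = 1..N with
#' N = floor(voicesPerOctave * log2(periodMax / periodMin)); strictly
#' increasing, ratio 2^(1/voices) between neighbours, periodMin excluded and
#' periodMax included when it falls on a voice.
#'
#' @slot samplingPeriod numeric, hours per sample (1 for hourly JIDs).
#' @slot voicesPerOctave numeric.
#' @slot periodMin,periodMax numeric, hours.
#' @slot periods numeric, hours.
#'
#' @seealso [periodGrid()]
#' @exportClass PeriodGrid
setClass("PeriodGrid",
  representation(
    samplingPeriod = "numeric",
    voicesPerOctave = "numeric",
    periodMin = "numeric", periodMax = "numeric",
    periods = "numeric"
  )
)

setValidity("PeriodGrid", function(object) {
  msg <- character(0)
  p <- object@periods
  if (any(diff(p) <= 0)) msg <- c(msg, "periods must be strictly increasing")
  if (length(p)) {
    if (min(p) <= object@periodMin) msg <- c(msg, "periods must exceed periodMin")
    if (max(p) > object@periodMax * (1 + 1e-12)) msg <- c(msg, "periods must not exceed periodMax")
    r <- diff(log2(p)) * object@voicesPerOctave
    if (length(r) && max(abs(r - 1)) > 1e-8)
      msg <- c(msg, "consecutive periods must differ by 2^(1/voices)")
  }
  if (length(msg)) msg else TRUE
})

#' Per-bin wavelet periodogram tensor
#'
#' Time-averaged continuous-wavelet periodogram for every JID bin:
#' P(period) = sqrt(mean |S|) with the temporal mean taken outside the cone
#' of influence. \code{kind} distinguishes raw power from the
#' aperiodic-adjusted "power index" (raw minus block-bootstrap ensemble
#' mean), which may be negative.
#'
#' Power is stored as a T x B matrix whose columns follow column-major
#' raster order of the JID grid (bin (r, c) -> column r + (c-1) * nSteps);
#' [powerArray()] returns the nSteps x nSteps x T view.
#'
#' @slot grid a [JIDGrid-class].
#' @slot periodGrid a [PeriodGrid-class].
#' @slot power numeric matrix T x B (B = nSteps^2). Rows of unusable periods
#'   (cone of influence leaves no samples) are NaN.
#' @slot kind \code{"raw"} or \code{"adjusted"}.
#'
#' @seealso [jidPeriodograms()], [aperiodicAdjust()]
#' @exportClass PeriodogramTensor
setClass("PeriodogramTensor",
  representation(
    grid = "JIDGrid",
    periodGrid = "PeriodGrid",
    power = "matrix",
    kind = "character"
  )
)

setValidity("PeriodogramTensor", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("raw", "adjusted"))
    msg <- c(msg, "kind must be 'raw' or 'adjusted'")
  if (nrow(object@power) != length(object@periodGrid@periods))
    msg <- c(msg, "power rows must match the period grid")
  if (ncol(object@power) != object@grid@nSteps^2)
    msg <- c(msg, "power columns must equal nSteps^2")
  if (object@kind == "raw" && any(object@power < -1e-12, na.rm = TRUE))
    msg <- c(msg, "raw power must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Block-bootstrap ensemble of periodograms
#'
#' Periodogram tensors of 24-hour block-bootstrapped copies of an hourly
#' JID. The ensemble mean estimates the aperiodic periodogram component;
#' elementwise two-tailed quantiles give pointwise significance thresholds.
#'
#' @slot power numeric array T x B x nBoot.
#' @slot grid a [JIDGrid-class].
#' @slot periodGrid a [PeriodGrid-class].
#' @slot blockHours numeric, bootstrap block length in hours.
#' @slot seed numeric.
#'
#' @seealso [bootstrapPeriodograms()]
#' @exportClass BootstrapEnsemble
setClass("BootstrapEnsemble",
  representation(
    power = "array",
    grid = "JIDGrid",
    periodGrid = "PeriodGrid",
    blockHours = "numeric",
    seed = "numeric"
  )
)

setValidity("BootstrapEnsemble", function(object) {
  d <- dim(object@power)
  msg <- character(0)
  if (length(d) != 3L) msg <- c(msg, "power must be T x B x nBoot")
  else {
    if (d[1] != length(object@periodGrid@periods))
      msg <- c(msg, "power rows must match the period grid")
    if (d[2] != object@grid@nSteps^2)
      msg <- c(msg, "power columns must equal nSteps^2")
  }
  if (length(msg)) msg else TRUE
})

#' Significant (bin, period) clusters
#'
#' Connected components of the pointwise significance mask on the
#' (JID row, JID column, period) lattice under face (6-)connectivity.
#' Components smaller than \code{minSize} bins are discarded; surviving
#' components are compared with the 97.5th percentile of the per-bootstrap
#' maximum cluster sizes (family-wise correction).
#'
#' @slot labels integer matrix T x B; 0 = background, k = cluster k.
#' @slot sizes integer vector, bins per retained cluster.
#' @slot significant logical vector, family-wise significance per cluster.
#' @slot fwThreshold numeric, 97.5th percentile of null max cluster sizes.
#' @slot nullMaxSizes numeric, per-bootstrap maximum cluster sizes.
#' @slot minSize numeric, minimum bins per retained cluster.
#' @slot alpha numeric, pointwise two-tailed level.
#' @slot grid a [JIDGrid-class].
#' @slot periodGrid a [PeriodGrid-class].
#'
#' @seealso [clusterCorrect()]
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(
    labels = "matrix",
    sizes = "numeric",
    significant = "logical",
    fwThreshold = "numeric",
    nullMaxSizes = "numeric",
    minSize = "numeric",
    alpha = "numeric",
    grid = "JIDGrid",
    periodGrid = "PeriodGrid"
  )
)

setValidity("ClusterSet", function(object) {
  msg <- character(0)
  if (length(object@sizes) != length(object@significant))
    msg <- c(msg, "sizes and significant must have equal length")
  k <- length(object@sizes)
  if (k && max(object@labels) > k) msg <- c(msg, "labels exceed cluster count")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Factorization containers
# ---------------------------------------------------------------------------

#' Period-sliced, shifted periodogram matrix
#'
#' The adjusted periodogram tensor sliced to a multiday period band and
#' reshaped to T' x B (rows = retained periods, columns = JID bins in
#' column-major raster order), then globally shifted up by subtracting its
#' minimum so all entries are non-negative — the input to NNMF.
#'
#' @slot values numeric matrix T' x B, all >= 0.
#' @slot periods numeric, hours, the retained period slice.
#' @slot shift numeric, the global minimum that was subtracted.
#' @slot nSteps numeric, JID bins per dimension (raster order contract).
#'
#' @seealso [sliceReshape()]
#' @exportClass RhythmMatrix
setClass("RhythmMatrix",
  representation(
    values = "matrix",
    periods = "numeric",
    shift = "numeric",
    nSteps = "numeric"
  )
)

setValidity("RhythmMatrix", function(object) {
  msg <- character(0)
  if (nrow(object@values) != length(object@periods))
    msg <- c(msg, "values rows must match periods")
  if (any(object@values < -1e-10))
    msg <- c(msg, "values must be non-negative after shifting")
  if (length(msg)) msg else TRUE
})

#' Stability-selected NNMF of a rhythm matrix
#'
#' W (T' x R) holds the meta-rhythms (periodogram-shaped components),
#' H (R x B) the meta-behaviors (loadings over JID bins). Meta-rhythm
#' columns are normalized to unit maximum with the scale absorbed into H.
#'
#' @slot W,H numeric matrices, non-negative.
#' @slot rank numeric.
#' @slot cvCurve data.frame (rank, meanTestError) or empty when the rank
#'   was fixed by the caller.
#' @slot stability numeric, median pairwise similarity of the chosen run.
#' @slot periods numeric, hours, row axis of W.
#' @slot seed numeric.
#'
#' @seealso [starNNMF()], [selectRank()]
#' @exportClass MetaRhythmSet
setClass("MetaRhythmSet",
  representation(
    W = "matrix", H = "matrix",
    rank = "numeric",
    cvCurve = "data.frame",
    stability = "numeric",
    periods = "numeric",
    seed = "numeric"
  )
)

setValidity("MetaRhythmSet", function(object) {
  msg <- character(0)
  if (ncol(object@W) != object@rank || nrow(object@H) != object@rank)
    msg <- c(msg, "W/H dimensions must match rank")
  if (nrow(object@W) != length(object@periods))
    msg <- c(msg, "W rows must match periods")
  if (any(object@W < 0) || any(object@H < 0))
    msg <- c(msg, "W and H must be non-negative")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Population-level containers
# ---------------------------------------------------------------------------

#' Population clustering of pooled meta-rhythms
#'
#' Meta-rhythms pooled across subjects, z-scored, mapped to Daubechies-4
#' discrete-wavelet coefficients and k-means clustered; k is selected by
#' mean silhouette. Each cluster is summarised by its mean curve, peak
#' period, and the period range where the mean exceeds its own 95th
#' percentile.
#'
#' @slot k numeric, number of clusters.
#' @slot assignments data.frame (subjectId, component, cluster).
#' @slot clusterMeans numeric matrix T' x k of mean z-scored curves.
#' @slot periods numeric, hours.
#' @slot peakPeriod,rangeMin,rangeMax numeric per cluster, days.
#' @slot incomplete logical per cluster, TRUE when the over-threshold range
#'   abuts the period axis edge (peak not interpretable).
#' @slot silhouette data.frame (k, meanSilhouette).
#'
#' @seealso [clusterMetaRhythms()]
#' @exportClass RhythmClusterSet
setClass("RhythmClusterSet",
  representation(
    k = "numeric",
    assignments = "data.frame",
    clusterMeans = "matrix",
    periods = "numeric",
    peakPeriod = "numeric",
    rangeMin = "numeric",
    rangeMax = "numeric",
    incomplete = "logical",
    silhouette = "data.frame"
  )
)

#' Pairwise phase-coherence result for one rhythm band
#'
#' Wavelet magnitude-squared coherence between pairs of subjects' reference
#' JID-bin series, averaged over a period band, with one-tailed
#' block-bootstrap significance and rates split by gender-pair class.
#'
#' @slot band numeric length 2, period band in days.
#' @slot pairs data.frame (subjectA, subjectB, pairClass, coherence,
#'   threshold, significant).
#' @slot rates data.frame (pairClass, nPairs, rateSignificant).
#'
#' @seealso [cohortCoherence()]
#' @exportClass CoherenceResult
setClass("CoherenceResult",
  representation(
    band = "numeric",
    pairs = "data.frame",
    rates = "data.frame"
  )
)

setValidity("CoherenceResult", function(object) {
  msg <- character(0)
  p <- object@pairs
  if (nrow(p)) {
    if (any(p$coherence < -1e-9 | p$coherence > 1 + 1e-9))
      msg <- c(msg, "coherence must lie in [0, 1]")
    key <- paste(pmin(p$subjectA, p$subjectB), pmax(p$subjectA, p$subjectB))
    if (anyDuplicated(key)) msg <- c(msg, "each unordered pair at most once")
  }
  if (length(msg)) msg else TRUE
})
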