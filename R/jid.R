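# Hourly joint-interval distributions (JIDs).
#
# Consecutive inter-touch intervals (ITI_k, ITI_{k+1}) within screen-on
# sessions, log10-transformed, are accumulated into consecutive 1-hour bins
# and smoothed with an isotropic Gaussian KDE (bandwidth 0.1 in log10
# units), evaluated at the centers of an equal-log10-step grid. Mass
# leaking past the truncation window is not renormalized.

#' Construct a JID grid
#'
#' @param axisMin,axisMax log10(ms) window bounds; the defaults span
#'   10^1.5 ms (~30 ms) to 10^5 ms (~2 min), the upper bound matching the
#'   99th percentile of observed inter-touch intervals.
#' @param nSteps bins per dimension (50 gives the standard 2500-bin space).
#' @return a [JIDGrid-class]; bin centers sit at the midpoints of
#'   \code{nSteps} equal log10 steps.
#' @examples
#' g <- jidGrid()
#' length(binCenters(g))^2  # 2500
#' @export
jidGrid <- function(axisMin = 1.5, axisMax = 5.0, nSteps = 50L) {
  step <- (axisMax - axisMin) / nSteps
  centers <- axisMin + step * (seq_len(nSteps) - 0.5)
  new("JIDGrid", axisMin = axisMin, axisMax = axisMax,
      nSteps = as.numeric(nSteps), binCenters = centers)
}

#' Partition touches into screen-on sessions
#'
#' Touches are grouped by their enclosing screen_on -> screen_off span, so
#' intervals never cross session boundaries. An unmatched trailing
#' screen_on closes at the end of the stream with a warning; touches
#' outside any span are ignored with a warning.
#'
#' @param stream a [TouchEventStream-class].
#' @return list of numeric vectors, each the ordered touch timestamps (ms)
#'   of one session (sessions with zero touches are dropped).
#' @export
sessionize <- function(stream) {
  ev <- events(stream)
  if (!nrow(ev)) return(list())
  ts <- ev$timestampMs
  onT <- ts[ev$type == "screen_on"]
  offT <- ts[ev$type == "screen_off"]
  touch <- ts[ev$type == "touch"]
  if (!length(touch)) return(list())
  if (length(onT) > length(offT)) {
    warning("unmatched screen_on; closing final session at stream end")
    offT <- c(offT, max(ts))
  } else if (length(offT) > length(onT)) {
    warning("screen_off without screen_on; ignoring leading off event(s)")
    offT <- offT[(length(offT) - length(onT) + 1):length(offT)]
  }
  if (!length(onT)) return(list())
  # which session does each touch fall into?
  sess <- findInterval(touch, onT)
  inSpan <- sess >= 1 & touch <= offT[pmax(sess, 1)]
  if (any(!inSpan))
    warning(sum(!inSpan), " touch(es) outside any screen-on span dropped")
  out <- split(touch[inSpan], sess[inSpan])
  unname(out[lengths(out) > 0])
}

#' Consecutive-interval pairs per hour
#'
#' Within each session, interval k is paired with interval k+1; both
#' coordinates are log10(ms). A pair is assigned to the hour containing the
#' onset of interval k, so every pair lands in exactly one hour.
#' Non-positive intervals (duplicate timestamps) are dropped and counted.
#'
#' @param sessions list of per-session touch timestamp vectors (ms), as
#'   returned by [sessionize()].
#' @return list with \code{pairs}, a data.frame (hour = UTC epoch hour,
#'   x = log10 ITI_k, y = log10 ITI_{k+1}), and \code{dropped}, the count
#'   of non-positive intervals discarded.
#' @export
hourlyPairs <- function(sessions) {
  hour <- x <- y <- numeric(0)
  dropped <- 0L
  for (s in sessions) {
    if (length(s) < 3L) next
    iti <- diff(s)
    onset <- s[-length(s)]
    pos <- iti > 0
    dropped <- dropped + sum(!pos)
    iti <- iti[pos]
    onset <- onset[pos]
    if (length(iti) < 2L) next
    k <- seq_len(length(iti) - 1L)
    x <- c(x, log10(iti[k]))
    y <- c(y, log10(iti[k + 1L]))
    hour <- c(hour, floor(onset[k] / 3600e3))
  }
  list(pairs = data.frame(hour = hour, x = x, y = y), dropped = dropped)
}

#' Gaussian-kernel JID estimate for one hour
#'
#' Isotropic bivariate Gaussian KDE in log10 x log10 space, normalized as a
#' probability density and evaluated at the grid's bin centers. Because the
#' kernel is separable, the 2-D evaluation is the cross-product of two 1-D
#' kernel matrices.
#'
#' @param x,y log10(ms) coordinates of the hour's pairs.
#' @param grid a [JIDGrid-class].
#' @param bandwidth Gaussian kernel standard deviation in log10 units.
#' @return numeric nSteps x nSteps matrix of density values (rows = ITI_k
#'   axis, columns = ITI_{k+1} axis); integrates to <= 1 over the window.
#' @export
estimateJID <- function(x, y, grid, bandwidth = 0.1) {
  n <- length(x)
  if (n == 0L) stop("estimateJID needs at least one pair")
  stopifnot(length(y) == n)
  cx <- grid@binCenters
  Kx <- stats::dnorm(outer(cx, x, "-"), sd = bandwidth)  # nSteps x n
  Ky <- stats::dnorm(outer(cx, y, "-"), sd = bandwidth)
  (Kx %*% t(Ky)) / n
}

#' Build the hourly JID tensor of a stream
#'
#' Hours run from the hour of the first event to the hour of the last event
#' inclusive, giving a regular hourly sampling grid of length D. Hours
#' without interval pairs (including recording gaps) get an all-zero
#' density and \code{valid = FALSE}; downstream wavelet analysis consumes
#' the zeros so the sampling grid stays regular.
#'
#' @param stream a [TouchEventStream-class].
#' @param grid a [JIDGrid-class].
#' @param bandwidth KDE bandwidth in log10 units.
#' @return an [HourlyJID-class].
#' @examples
#' jid <- buildJID(exampleStream(), jidGrid(nSteps = 20L))
#' @export
buildJID <- function(stream, grid = jidGrid(), bandwidth = 0.1) {
  ev <- events(stream)
  if (!nrow(ev)) stop("empty stream: no events")
  hp <- hourlyPairs(sessionize(stream))
  if (!nrow(hp$pairs))
    stop("no interval pairs: every session has fewer than 3 touches")
  h0 <- floor(min(ev$timestampMs) / 3600e3)
  h1 <- floor(max(ev$timestampMs) / 3600e3)
  hours <- seq(h0, h1)
  D <- length(hours)
  n <- as.integer(grid@nSteps)
  dens <- array(0, dim = c(n, n, D))
  valid <- rep(FALSE, D)
  byHour <- split(hp$pairs[c("x", "y")], factor(hp$pairs$hour, levels = hours))
  for (d in which(vapply(byHour, nrow, integer(1)) > 0)) {
    p <- byHour[[d]]
    dens[, , d] <- estimateJID(p$x, p$y, grid, bandwidth)
    valid[d] <- TRUE
  }
  new("HourlyJID", grid = grid, hours = as.numeric(hours),
      density = dens, valid = valid, droppedPairs = as.numeric(hp$dropped))
}
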