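# Block-bootstrap null statistics and cluster-based correction.
#
# The hourly JID tensor is resampled in contiguous 24-hour blocks (all 2500
# bin series jointly, preserving within-day structure while destroying
# multi-day phase), a periodogram is computed per bootstrap, the ensemble
# mean estimates the aperiodic component, elementwise two-tailed quantiles
# give pointwise significance, and family-wise correction uses the maximum
# size of significant connected components on the (row, col, period)
# lattice across bootstraps.

#' Block-resampling indices
#'
#' Draws hours in contiguous \code{blockHours}-long blocks with
#' replacement and concatenates them, truncating the final block so the
#' output has length D. \code{"aligned"} draws from the non-overlapping
#' day-aligned windows of the recording, preserving time-of-day structure
#' (used for the periodogram null, so circadian power cancels in the
#' aperiodic adjustment). \code{"moving"} draws blocks starting anywhere,
#' which additionally scrambles diurnal phase (used for the coherence
#' null, where day-aligned blocks would leave 1-day phase alignment
#' intact).
#'
#' @param D series length in samples (hours).
#' @param blockHours block length (samples).
#' @param style \code{"aligned"} or \code{"moving"}.
#' @return integer vector of length D.
#' @export
blockResampleIndices <- function(D, blockHours = 24,
                                 style = c("aligned", "moving")) {
  style <- match.arg(style)
  if (D < blockHours) stop("series shorter than one block")
  w <- as.integer(blockHours)
  D <- as.integer(D)
  nDraw <- ceiling(D / w)
  if (style == "aligned") {
    starts <- (sample.int(D %/% w, nDraw, replace = TRUE) - 1L) * w + 1L
  } else {
    starts <- sample.int(D - w + 1L, nDraw, replace = TRUE)
  }
  idx <- as.vector(outer(seq_len(w) - 1L, starts, "+"))
  idx[seq_len(D)]
}

#' Block-bootstrap an hourly JID
#'
#' All bin series are resampled with the same block indices, so hours stay
#' jointly shuffled.
#'
#' @param jid an [HourlyJID-class].
#' @param blockHours block length in hours.
#' @param seed optional seed (set before drawing indices).
#' @return an [HourlyJID-class] of the same length.
#' @export
blockBootstrapJID <- function(jid, blockHours = 24, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- length(jid@hours)
  idx <- blockResampleIndices(D, blockHours)
  new("HourlyJID", grid = jid@grid, hours = jid@hours,
      density = jid@density[, , idx, drop = FALSE],
      valid = jid@valid[idx], droppedPairs = jid@droppedPairs)
}

#' Block-bootstrap ensemble of periodograms
#'
#' @param jid an [HourlyJID-class].
#' @param pgrid a [PeriodGrid-class].
#' @param nBoot number of bootstrap replicates.
#' @param blockHours block length in hours.
#' @param seed RNG seed for the whole ensemble.
#' @return a [BootstrapEnsemble-class].
#' @export
bootstrapPeriodograms <- function(jid, pgrid, nBoot = 100, blockHours = 24,
                                  seed = 1L) {
  X <- densityMatrix(jid)
  D <- nrow(X)
  if (D < blockHours) stop("recording shorter than one bootstrap block")
  set.seed(seed)
  Tn <- length(pgrid@periods)
  B <- ncol(X)
  P <- array(NA_real_, dim = c(Tn, B, nBoot))
  for (b in seq_len(nBoot)) {
    idx <- blockResampleIndices(D, blockHours)
    P[, , b] <- cwtPower(X[idx, , drop = FALSE], pgrid)
  }
  new("BootstrapEnsemble", power = P, grid = jid@grid, periodGrid = pgrid,
      blockHours = blockHours, seed = as.numeric(seed))
}

#' Ensemble mean (aperiodic component estimate)
#' @param ensemble a [BootstrapEnsemble-class].
#' @return numeric matrix T x B.
#' @export
ensembleMean <- function(ensemble) {
  rowMeans(ensemble@power, dims = 2)
}

# Elementwise type-7 quantiles across the bootstrap dimension.
# Returns list(qLow, qHigh) as T x B matrices.
.ensembleQuantiles <- function(ensemble, alpha) {
  P <- ensemble@power
  d <- dim(P)
  M <- matrix(P, d[1] * d[2], d[3])
  S <- t(apply(M, 1, sort, method = "quick", na.last = TRUE))  # NaN rows stay NA
  q1 <- .sortedQuantile(S, alpha / 2)
  q2 <- .sortedQuantile(S, 1 - alpha / 2)
  list(qLow = matrix(q1, d[1], d[2]), qHigh = matrix(q2, d[1], d[2]))
}

# Type-7 quantile from row-sorted matrix.
.sortedQuantile <- function(S, p) {
  n <- ncol(S)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  g <- h - floor(h)
  if (lo >= n) return(S[, n])
  S[, lo] * (1 - g) + S[, lo + 1] * g
}

#' Subtract the aperiodic component from a raw periodogram
#'
#' The mean of the block-bootstrapped periodograms estimates the aperiodic
#' component; subtracting it elementwise yields the adjusted periodogram
#' ("power index"), which may be negative.
#'
#' @param real a raw [PeriodogramTensor-class].
#' @param ensemble a [BootstrapEnsemble-class] of the same geometry.
#' @return a [PeriodogramTensor-class] of kind \code{"adjusted"}.
#' @export
aperiodicAdjust <- function(real, ensemble) {
  if (real@kind != "raw") stop("aperiodicAdjust expects a raw periodogram")
  if (!identical(dim(real@power), dim(ensemble@power)[1:2]))
    stop("periodogram and ensemble shapes differ")
  adj <- real@power - ensembleMean(ensemble)
  new("PeriodogramTensor", grid = real@grid, periodGrid = real@periodGrid,
      power = adj, kind = "adjusted")
}

#' Pointwise two-tailed significance mask
#'
#' TRUE where the real power falls below the alpha/2 or above the
#' 1 - alpha/2 bootstrap quantile of that (bin, period). Unusable (NaN)
#' periods are FALSE.
#'
#' @param real a raw [PeriodogramTensor-class].
#' @param ensemble a [BootstrapEnsemble-class].
#' @param alpha two-tailed pointwise level.
#' @return logical matrix T x B.
#' @export
pointwiseMask <- function(real, ensemble, alpha = 0.05) {
  nBoot <- dim(ensemble@power)[3]
  if (nBoot < 40) stop("need at least 40 bootstraps for stable quantiles")
  if (alpha >= 1) {
    m <- is.finite(real@power)
    return(m)
  }
  q <- .ensembleQuantiles(ensemble, alpha)
  m <- real@power < q$qLow | real@power > q$qHigh
  m[!is.finite(m)] <- FALSE
  m
}

# ---------------------------------------------------------------------------
# Connected components on the (row, col, period) lattice, 6-connectivity.
# ---------------------------------------------------------------------------

# Label connected components of a logical array under face connectivity.
# Frontier-propagation BFS, vectorized over the frontier.
.labelArray <- function(arr) {
  d <- dim(arr)
  nr <- d[1]; nc <- d[2]; nt <- d[3]
  labels <- array(0L, d)
  todo <- which(arr)
  cur <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    labels[start] <- cur
    frontier <- start
    while (length(frontier)) {
      i0 <- frontier - 1L
      r <- i0 %% nr
      rest <- i0 %/% nr
      cc <- rest %% nc
      tt <- rest %/% nc
      nbr <- c(frontier[r > 0] - 1L,
               frontier[r < nr - 1L] + 1L,
               frontier[cc > 0] - nr,
               frontier[cc < nc - 1L] + nr,
               frontier[tt > 0] - nr * nc,
               frontier[tt < nt - 1L] + nr * nc)
      nbr <- unique(nbr[arr[nbr] & labels[nbr] == 0L])
      labels[nbr] <- cur
      frontier <- nbr
    }
  }
  labels
}

# mask: T x B logical; returns list(labels [n,n,T] array, sizes).
.labelMask <- function(mask, nSteps) {
  Tn <- nrow(mask)
  arr <- array(t(mask), dim = c(nSteps, nSteps, Tn))
  labels <- .labelArray(arr)
  sizes <- tabulate(labels)
  list(labels = labels, sizes = sizes)
}

# Drop components below minSize, relabel 1..K by decreasing size.
.retainClusters <- function(lab, minSize) {
  keep <- which(lab$sizes >= minSize)
  keep <- keep[order(lab$sizes[keep], decreasing = TRUE)]
  map <- integer(length(lab$sizes))
  map[keep] <- seq_along(keep)
  newLabels <- array(0L, dim(lab$labels))
  nz <- lab$labels != 0L
  newLabels[nz] <- map[lab$labels[nz]]
  list(labels = newLabels, sizes = lab$sizes[keep])
}

# Max size among components >= minSize (0 if none).
.maxClusterSize <- function(mask, nSteps, minSize) {
  s <- .labelMask(mask, nSteps)$sizes
  s <- s[s >= minSize]
  if (length(s)) max(s) else 0
}

#' Cluster-based multiple-comparison correction
#'
#' Pointwise masks are computed identically for the real periodogram and
#' for each bootstrap replicate (against the ensemble quantiles);
#' connected components under face (6-)connectivity on the (JID row, JID
#' column, period) lattice smaller than \code{minSize} bins are discarded;
#' the per-bootstrap maximum component size forms the null, and real
#' clusters larger than its 97.5th percentile are family-wise significant.
#'
#' @param real a raw [PeriodogramTensor-class].
#' @param ensemble a [BootstrapEnsemble-class].
#' @param alpha pointwise two-tailed level.
#' @param minSize minimum bins per retained cluster.
#' @param fwProb quantile of the null max-cluster distribution.
#' @return a [ClusterSet-class].
#' @export
clusterCorrect <- function(real, ensemble, alpha = 0.05, minSize = 5,
                           fwProb = 0.975) {
  n <- as.integer(real@grid@nSteps)
  nBoot <- dim(ensemble@power)[3]
  if (nBoot < 40) stop("need at least 40 bootstraps for stable quantiles")
  q <- .ensembleQuantiles(ensemble, alpha)
  realMask <- real@power < q$qLow | real@power > q$qHigh
  realMask[!is.finite(realMask)] <- FALSE

  nullMax <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    mb <- ensemble@power[, , b] < q$qLow | ensemble@power[, , b] > q$qHigh
    mb[!is.finite(mb)] <- FALSE
    nullMax[b] <- .maxClusterSize(mb, n, minSize)
  }
  fw <- as.numeric(stats::quantile(nullMax, fwProb, type = 7))

  lab <- .retainClusters(.labelMask(realMask, n), minSize)
  Tn <- nrow(real@power)
  labMat <- t(matrix(lab$labels, n * n, Tn))
  new("ClusterSet",
      labels = labMat,
      sizes = as.numeric(lab$sizes),
      significant = lab$sizes > fw,
      fwThreshold = fw,
      nullMaxSizes = nullMax,
      minSize = minSize, alpha = alpha,
      grid = real@grid, periodGrid = real@periodGrid)
}

#' Periods covered by one cluster
#' @param cs a [ClusterSet-class].
#' @param id cluster id.
#' @return numeric vector of periods (hours) where the cluster has bins.
#' @export
clusterPeriods <- function(cs, id) {
  rows <- which(apply(cs@labels == id, 1, any))
  cs@periodGrid@periods[rows]
}
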