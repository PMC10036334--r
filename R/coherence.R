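# Pairwise wavelet phase coherence.
#
# For a rhythm band, each eligible subject contributes the hourly density
# series of a reference JID bin (maximum power index inside the largest
# band-overlapping significant cluster). Magnitude-squared wavelet
# coherence — cross-spectrum smoothed in time (~one period) and across
# adjacent scales, normalized by the smoothed auto-spectra — is averaged
# over the band and outside the cone of influence, and tested one-tailed
# against a 24-hour block-bootstrap null that resamples one member of the
# pair (sufficient to break cross-subject phase alignment).

#' Reference JID bin for a subject and band
#'
#' Among family-wise significant clusters with bins at periods inside the
#' band, takes the cluster with the most in-band bins; within it, the bin
#' whose power index (maximum over in-band periods) is largest.
#'
#' @param cs a [ClusterSet-class].
#' @param adjusted the subject's adjusted [PeriodogramTensor-class].
#' @param bandDays numeric length 2, period band in days.
#' @return list(row, col) grid coordinates, or NULL when no significant
#'   cluster intersects the band (subject excluded from this band).
#' @export
selectReferenceBin <- function(cs, adjusted, bandDays) {
  ph <- cs@periodGrid@periods
  inBand <- ph >= bandDays[1] * 24 & ph <= bandDays[2] * 24
  if (!any(inBand)) return(NULL)
  sig <- which(cs@significant)
  if (!length(sig)) return(NULL)
  sub <- cs@labels[inBand, , drop = FALSE]
  nPix <- vapply(sig, function(id) sum(sub == id), numeric(1))
  if (all(nPix == 0)) return(NULL)
  id <- sig[which.max(nPix)]
  pw <- adjusted@power[inBand, , drop = FALSE]
  pw[sub != id] <- -Inf
  cell <- arrayInd(which.max(pw), dim(pw))
  n <- as.integer(cs@grid@nSteps)
  bin <- cell[2]
  list(row = (bin - 1L) %% n + 1L, col = (bin - 1L) %/% n + 1L)
}

#' Hourly density series of one JID bin
#' @param jid an [HourlyJID-class].
#' @param row,col grid coordinates.
#' @return numeric vector of length D.
#' @export
binSeries <- function(jid, row, col) {
  as.numeric(jid@density[row, col, ])
}

# Centered running mean via cumulative sums; NA where the window is
# incomplete (those samples sit inside the cone of influence anyway).
.runMean <- function(v, w) {
  if (w <= 1) return(v)
  n <- length(v)
  h <- (w - 1) / 2
  if (n < w) return(rep(NA_real_, n))
  cs <- c(0, cumsum(v))
  out <- rep(NA_real_, n)
  i <- (h + 1):(n - h)
  out[i] <- (cs[i + h + 1] - cs[i - h]) / w
  out
}

# Moving-average smoothing of a (time x scale) matrix: per-scale boxcar in
# time with window ~ one period, then boxcar across adjacent scales.
.smoothTS <- function(M, winTime, winScale) {
  for (j in seq_len(ncol(M)))
    M[, j] <- .runMean(M[, j], winTime[j])
  if (winScale > 1 && ncol(M) > 1) {
    h <- (winScale - 1) / 2
    out <- matrix(NA_real_, nrow(M), ncol(M))
    for (j in seq_len(ncol(M))) {
      if (j - h < 1 || j + h > ncol(M)) next
      out[, j] <- rowMeans(M[, (j - h):(j + h), drop = FALSE])
    }
    M <- out
  }
  M
}

# Precompute one side of the coherence: raw coefficients + smoothed
# auto-spectrum for the selected scale indices.
.coherenceSide <- function(x, pgrid, select, winTime, winScale) {
  cc <- cwtCoeffs(x, pgrid, select)
  Sxx <- .smoothTS(Mod(cc$coef)^2, winTime, winScale)
  list(coef = cc$coef, auto = Sxx, coi = cc$coi)
}

.coherenceFromSides <- function(a, b, winTime, winScale, bandCols) {
  cross <- a$coef * Conj(b$coef)
  Sxy <- .smoothTS(Re(cross), winTime, winScale) +
    1i * .smoothTS(Im(cross), winTime, winScale)
  C2 <- Mod(Sxy)^2 / (a$auto * b$auto)
  ok <- a$coi & b$coi & is.finite(C2)
  C2 <- pmin(pmax(C2, 0), 1)
  vals <- C2[, bandCols, drop = FALSE][ok[, bandCols, drop = FALSE]]
  if (!length(vals)) stop("no usable coherence samples in the band")
  mean(vals)
}

# Scale selection and smoothing windows for a band.
.coherenceSetup <- function(D, pgrid, bandDays, scaleSmoothOctaves = 0.6) {
  ph <- pgrid@periods
  inBand <- which(ph >= bandDays[1] * 24 & ph <= bandDays[2] * 24)
  if (!length(inBand)) stop("band contains no periods of the grid")
  if (D < 2 * bandDays[2] * 24)
    stop("overlap shorter than twice the band's maximum period")
  winScale <- max(1, round(scaleSmoothOctaves * pgrid@voicesPerOctave))
  if (winScale %% 2 == 0) winScale <- winScale + 1
  margin <- (winScale - 1) / 2
  sel <- max(1, min(inBand) - margin):min(length(ph), max(inBand) + margin)
  winTime <- pmax(1, round(ph[sel] / pgrid@samplingPeriod))
  winTime <- winTime + (winTime %% 2 == 0)
  winTime <- pmin(winTime, D - (1 - D %% 2))
  list(select = sel, winTime = winTime, winScale = winScale,
       bandCols = match(inBand, sel))
}

#' Band-averaged wavelet coherence of two hourly series
#'
#' @param xa,xb numeric hourly series on a common calendar window.
#' @param bandDays numeric length 2, period band in days.
#' @param pgrid a [PeriodGrid-class].
#' @param scaleSmoothOctaves width (octaves) of the across-scale smoother.
#' @return scalar mean magnitude-squared coherence in \[0, 1\].
#' @export
pairBandCoherence <- function(xa, xb, bandDays, pgrid,
                              scaleSmoothOctaves = 0.6) {
  stopifnot(length(xa) == length(xb))
  st <- .coherenceSetup(length(xa), pgrid, bandDays, scaleSmoothOctaves)
  a <- .coherenceSide(xa, pgrid, st$select, st$winTime, st$winScale)
  b <- .coherenceSide(xb, pgrid, st$select, st$winTime, st$winScale)
  .coherenceFromSides(a, b, st$winTime, st$winScale, st$bandCols)
}

#' Block-bootstrap significance of a pair's band coherence
#'
#' The null resamples one member of the pair in 24-hour blocks, which
#' preserves its within-day structure but destroys cross-subject phase
#' alignment; the pair is significant when the observed mean coherence
#' exceeds the null's 95th percentile (one-tailed alpha = 0.05).
#'
#' @param xa,xb numeric hourly series on a common calendar window.
#' @param bandDays numeric length 2, days.
#' @param pgrid a [PeriodGrid-class].
#' @param nBoot bootstrap replicates (>= 40).
#' @param blockHours block length.
#' @param seed RNG seed.
#' @param prob null quantile (default 0.95).
#' @return list: \code{coherence}, \code{threshold}, \code{significant},
#'   \code{null} (the bootstrap values).
#' @export
coherenceSignificance <- function(xa, xb, bandDays, pgrid, nBoot = 100,
                                  blockHours = 24, seed = 1L, prob = 0.95) {
  if (nBoot < 40) stop("need at least 40 bootstraps")
  st <- .coherenceSetup(length(xa), pgrid, bandDays)
  a <- .coherenceSide(xa, pgrid, st$select, st$winTime, st$winScale)
  b <- .coherenceSide(xb, pgrid, st$select, st$winTime, st$winScale)
  obs <- .coherenceFromSides(a, b, st$winTime, st$winScale, st$bandCols)
  set.seed(seed)
  null <- numeric(nBoot)
  for (k in seq_len(nBoot)) {
    idx <- blockResampleIndices(length(xb), blockHours, style = "moving")
    bb <- .coherenceSide(xb[idx], pgrid, st$select, st$winTime, st$winScale)
    null[k] <- .coherenceFromSides(a, bb, st$winTime, st$winScale, st$bandCols)
  }
  thr <- as.numeric(stats::quantile(null, prob, type = 7))
  list(coherence = obs, threshold = thr, significant = obs > thr,
       null = null)
}

#' Cohort-wide pairwise coherence for one rhythm band
#'
#' Evaluates every unordered pair of eligible subjects. When
#' \code{clusterSets} and \code{adjusted} are supplied, the reference bin
#' of each subject comes from [selectReferenceBin()] and subjects without
#' a band-overlapping significant cluster are excluded; alternatively pass
#' \code{refBins} directly. Pairs are classed FF/MM/FM from the streams'
#' gender labels.
#'
#' @param jids named list of [HourlyJID-class] (names = subject ids).
#' @param bandDays numeric length 2, days.
#' @param pgrid a [PeriodGrid-class].
#' @param clusterSets,adjusted optional named lists for reference-bin
#'   selection.
#' @param refBins optional named list of list(row, col).
#' @param genders optional named character vector.
#' @param nBoot bootstrap replicates per pair.
#' @param blockHours block length.
#' @param seed master seed; per-pair seeds are derived from it.
#' @return a [CoherenceResult-class].
#' @export
cohortCoherence <- function(jids, bandDays, pgrid,
                            clusterSets = NULL, adjusted = NULL,
                            refBins = NULL, genders = NULL,
                            nBoot = 100, blockHours = 24, seed = 1L) {
  ids <- names(jids)
  if (is.null(refBins)) {
    if (is.null(clusterSets) || is.null(adjusted))
      stop("need refBins, or clusterSets plus adjusted")
    refBins <- lapply(ids, function(id)
      selectReferenceBin(clusterSets[[id]], adjusted[[id]], bandDays))
    names(refBins) <- ids
  }
  eligible <- ids[!vapply(refBins[ids], is.null, logical(1))]
  if (length(eligible) < 2) stop("need at least 2 eligible subjects")
  excluded <- setdiff(ids, eligible)
  if (length(excluded))
    message("excluded (no significant cluster in band): ",
            paste(excluded, collapse = ", "))

  pairClass <- function(ga, gb) {
    g <- sort(c(ga, gb))
    if (any(is.na(g)) || any(!nzchar(g))) return("??")
    paste0(g[1], g[2])
  }
  set.seed(seed)
  pairSeeds <- sample.int(2147483600L, length(eligible)^2)
  rows <- list()
  np <- 0L
  for (i in seq_len(length(eligible) - 1)) {
    for (j in (i + 1):length(eligible)) {
      A <- eligible[i]; B <- eligible[j]
      hA <- jids[[A]]@hours; hB <- jids[[B]]@hours
      common <- intersect(hA, hB)
      if (length(common) < 2 * bandDays[2] * 24) next
      xa <- binSeries(jids[[A]], refBins[[A]]$row, refBins[[A]]$col)
      xb <- binSeries(jids[[B]], refBins[[B]]$row, refBins[[B]]$col)
      xa <- xa[match(common, hA)]
      xb <- xb[match(common, hB)]
      np <- np + 1L
      cs <- coherenceSignificance(xa, xb, bandDays, pgrid, nBoot = nBoot,
                                  blockHours = blockHours,
                                  seed = pairSeeds[np])
      ga <- if (is.null(genders)) NA_character_ else genders[[A]]
      gb <- if (is.null(genders)) NA_character_ else genders[[B]]
      rows[[np]] <- data.frame(
        subjectA = A, subjectB = B,
        pairClass = pairClass(ga, gb),
        coherence = cs$coherence, threshold = cs$threshold,
        significant = cs$significant, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subjectA = character(0), subjectB = character(0),
               pairClass = character(0), coherence = numeric(0),
               threshold = numeric(0), significant = logical(0))
  rates <- do.call(rbind, lapply(split(pairs, pairs$pairClass), function(d)
    data.frame(pairClass = d$pairClass[1], nPairs = nrow(d),
               rateSignificant = mean(d$significant))))
  if (is.null(rates))
    rates <- data.frame(pairClass = character(0), nPairs = numeric(0),
                        rateSignificant = numeric(0))
  new("CoherenceResult", band = bandDays, pairs = pairs, rates = rates)
}
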