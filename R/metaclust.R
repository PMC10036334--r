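# Population clustering of pooled meta-rhythms.
#
# Meta-rhythms from all subjects are z-scored, mapped to their full set of
# Daubechies-4 discrete-wavelet coefficients, and k-means clustered; the
# number of clusters maximizes the mean silhouette. Each cluster's mean
# curve yields a peak period and the period range where the mean exceeds
# its own 95th percentile; prevalence counts instances per subject.

# Daubechies-4 (8-tap) orthonormal decomposition low-pass filter.
.DB4_H <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997)

# One periodized analysis step: returns approx and detail (length n/2).
.dwtStep <- function(v) {
  n <- length(v)
  h <- .DB4_H
  g <- rev(h) * c(1, -1, 1, -1, 1, -1, 1, -1)
  a <- d <- numeric(n / 2)
  for (k in 0:7) {
    idx <- (2 * (seq_len(n / 2) - 1) + k) %% n + 1
    a <- a + h[k + 1] * v[idx]
    d <- d + g[k + 1] * v[idx]
  }
  list(a = a, d = d)
}

#' Daubechies-4 wavelet feature vector of a curve
#'
#' Full-depth periodized pyramid decomposition (levels while the signal is
#' even and at least the filter length), after reflecting the curve to the
#' next power-of-two length. The feature vector concatenates all detail
#' coefficients and the final approximation.
#'
#' @param v numeric curve.
#' @return numeric feature vector (length = padded length).
#' @export
dwtFeatures <- function(v) {
  n0 <- length(v)
  n <- 2^ceiling(log2(n0))
  if (n > n0) {
    refl <- rev(v)[seq_len(min(n - n0, n0))]
    v <- c(v, refl, rep(v[n0], n - n0 - length(refl)))
  }
  details <- list()
  a <- v
  while (length(a) >= 8 && length(a) %% 2 == 0) {
    st <- .dwtStep(a)
    details[[length(details) + 1L]] <- st$d
    a <- st$a
  }
  c(unlist(details), a)
}

#' z-score curves, excluding constants
#'
#' @param curves numeric matrix (rows = samples along the period axis,
#'   columns = curves) or list of equal-length vectors.
#' @return list: \code{curves}, matrix of standardized columns (mean 0,
#'   sd 1); \code{kept}, integer indices of non-constant inputs.
#' @export
zscoreCurves <- function(curves) {
  if (is.list(curves)) curves <- do.call(cbind, curves)
  sds <- apply(curves, 2, stats::sd)
  kept <- which(sds > 0)
  if (length(kept) < ncol(curves))
    warning(ncol(curves) - length(kept), " constant curve(s) excluded")
  z <- scale(curves[, kept, drop = FALSE])
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  list(curves = z, kept = kept)
}

#' Peak period and 95th-percentile range of a cluster mean curve
#'
#' @param curve numeric mean curve.
#' @param periodDays numeric period axis in days.
#' @return list: \code{peak}, \code{rangeMin}, \code{rangeMax} (days);
#'   \code{incomplete}, TRUE when the over-threshold range abuts an axis
#'   edge (peak not interpretable).
#' @export
peakAndRange <- function(curve, periodDays) {
  stopifnot(length(curve) == length(periodDays))
  if (max(curve) - min(curve) <= 0) stop("constant curve has no peak")
  thr <- as.numeric(stats::quantile(curve, 0.95, type = 7))
  idx <- which(curve > thr)
  if (!length(idx)) idx <- which.max(curve)
  list(peak = periodDays[which.max(curve)],
       rangeMin = periodDays[min(idx)],
       rangeMax = periodDays[max(idx)],
       incomplete = min(idx) == 1L || max(idx) == length(curve))
}

#' Cluster pooled meta-rhythms into common rhythm families
#'
#' @param curves matrix T' x m of meta-rhythm curves (columns), or list.
#' @param periodsH numeric period axis in hours (length T').
#' @param subjectIds character of length m, owner of each curve.
#' @param maxK largest candidate cluster count (silhouette search 2..maxK).
#' @param seed RNG seed (k-means restarts).
#' @param nstart k-means restarts per k.
#' @return a [RhythmClusterSet-class].
#' @export
clusterMetaRhythms <- function(curves, periodsH,
                               subjectIds = NULL, maxK = 12, seed = 1L,
                               nstart = 20) {
  if (is.list(curves)) curves <- do.call(cbind, curves)
  m <- ncol(curves)
  if (is.null(subjectIds)) subjectIds <- rep("?", m)
  stopifnot(length(subjectIds) == m, nrow(curves) == length(periodsH))
  z <- zscoreCurves(curves)
  Z <- z$curves
  m2 <- ncol(Z)
  maxK <- min(maxK, m2 - 1L)
  if (maxK < 2) stop("fewer curves than clusters: need at least 3 curves")
  feats <- t(apply(Z, 2, dwtFeatures))
  dmat <- stats::dist(feats)
  set.seed(seed)
  ks <- 2:maxK
  sil <- numeric(length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    fits[[i]] <- stats::kmeans(feats, ks[i], nstart = nstart, iter.max = 100)
    sil[i] <- mean(cluster::silhouette(fits[[i]]$cluster, dmat)[, 3])
  }
  bi <- which.max(sil)
  k <- ks[bi]
  cl <- fits[[bi]]$cluster
  means <- sapply(seq_len(k), function(j)
    rowMeans(Z[, cl == j, drop = FALSE]))
  pd <- periodsH / 24
  pr <- lapply(seq_len(k), function(j) peakAndRange(means[, j], pd))
  # order clusters by peak period
  o <- order(vapply(pr, `[[`, numeric(1), "peak"))
  relabel <- match(seq_len(k), o)
  assignments <- data.frame(
    subjectId = subjectIds[z$kept],
    component = z$kept,
    cluster = relabel[cl],
    stringsAsFactors = FALSE)
  new("RhythmClusterSet",
      k = k,
      assignments = assignments,
      clusterMeans = means[, o, drop = FALSE],
      periods = periodsH,
      peakPeriod = vapply(pr[o], `[[`, numeric(1), "peak"),
      rangeMin = vapply(pr[o], `[[`, numeric(1), "rangeMin"),
      rangeMax = vapply(pr[o], `[[`, numeric(1), "rangeMax"),
      incomplete = vapply(pr[o], `[[`, logical(1), "incomplete"),
      silhouette = data.frame(k = ks, meanSilhouette = sil))
}

#' Prevalence of rhythm families across subjects
#'
#' Per cluster: meta-rhythm counts per subject, percentage of subjects
#' with at least one instance (split by gender), and — when per-subject
#' significance [ClusterSet-class] objects are supplied — the share of
#' present subjects whose family-wise significant periodogram clusters
#' overlap the family's period range ("confirmed"; always a subset of
#' present).
#'
#' @param rcs a [RhythmClusterSet-class].
#' @param subjects data.frame with columns subjectId, gender (the
#'   prevalence denominator; subjects absent from the profile should not
#'   be listed).
#' @param clusterSets optional named list of [ClusterSet-class] keyed by
#'   subjectId.
#' @return list: \code{summary} data.frame (one row per rhythm family),
#'   \code{counts} subjects x clusters matrix, \code{confirmed} logical
#'   matrix (or NULL).
#' @export
prevalenceTable <- function(rcs, subjects, clusterSets = NULL) {
  ids <- subjects$subjectId
  k <- rcs@k
  counts <- matrix(0L, length(ids), k, dimnames = list(ids, NULL))
  a <- rcs@assignments
  for (i in seq_len(nrow(a))) {
    r <- match(a$subjectId[i], ids)
    if (!is.na(r)) counts[r, a$cluster[i]] <- counts[r, a$cluster[i]] + 1L
  }
  present <- counts > 0
  confirmed <- NULL
  if (!is.null(clusterSets)) {
    confirmed <- matrix(FALSE, length(ids), k, dimnames = list(ids, NULL))
    for (r in seq_along(ids)) {
      cs <- clusterSets[[ids[r]]]
      if (is.null(cs)) next
      sig <- which(cs@significant)
      if (!length(sig)) next
      for (j in seq_len(k)) {
        if (!present[r, j]) next
        lo <- rcs@rangeMin[j] * 24
        hi <- rcs@rangeMax[j] * 24
        for (id in sig) {
          cp <- clusterPeriods(cs, id)
          if (any(cp >= lo & cp <= hi)) {
            confirmed[r, j] <- TRUE
            break
          }
        }
      }
    }
  }
  isF <- subjects$gender %in% c("F", "f", "female", "Female")
  isM <- subjects$gender %in% c("M", "m", "male", "Male")
  summary <- data.frame(
    cluster = seq_len(k),
    peakDays = rcs@peakPeriod,
    rangeMinDays = rcs@rangeMin,
    rangeMaxDays = rcs@rangeMax,
    incomplete = rcs@incomplete,
    nMetaRhythms = colSums(counts),
    nPresent = colSums(present),
    pctPresent = 100 * colMeans(present),
    pctFemale = if (any(isF)) 100 * colMeans(present[isF, , drop = FALSE]) else NA,
    pctMale = if (any(isM)) 100 * colMeans(present[isM, , drop = FALSE]) else NA,
    nConfirmed = if (is.null(confirmed)) NA else colSums(confirmed))
  list(summary = summary, counts = counts, confirmed = confirmed)
}
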