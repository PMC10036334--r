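# Generics, accessors and show methods.

#' Bin centers of a JID grid
#' @param x a [JIDGrid-class] or object carrying one.
#' @return numeric vector of log10(ms) bin centers.
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname binCenters
#' @export
setMethod("binCenters", "JIDGrid", function(x) x@binCenters)

#' Periods of a period grid (hours)
#' @param x a [PeriodGrid-class] or object carrying one.
#' @return numeric vector of periods in hours.
#' @export
setGeneric("periods", function(x) standardGeneric("periods"))

#' @rdname periods
#' @export
setMethod("periods", "PeriodGrid", function(x) x@periods)

#' @rdname periods
#' @export
setMethod("periods", "PeriodogramTensor", function(x) x@periodGrid@periods)

#' @rdname periods
#' @export
setMethod("periods", "RhythmMatrix", function(x) x@periods)

#' @rdname periods
#' @export
setMethod("periods", "MetaRhythmSet", function(x) x@periods)

#' Event table of a touch event stream
#' @param x a [TouchEventStream-class].
#' @return data.frame with columns timestampMs, type.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname events
#' @export
setMethod("events", "TouchEventStream", function(x) x@events)

#' Subject identifier
#' @param x an object with a subject id.
#' @return character scalar.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname subjectId
#' @export
setMethod("subjectId", "TouchEventStream", function(x) x@subjectId)

#' Hour axis of an hourly JID (UTC epoch hours)
#' @param x a [HourlyJID-class].
#' @return numeric vector of epoch hours.
#' @export
setGeneric("hourAxis", function(x) standardGeneric("hourAxis"))

#' @rdname hourAxis
#' @export
setMethod("hourAxis", "HourlyJID", function(x) x@hours)

#' Validity flags of the hourly JID (hour had >= 1 interval pair)
#' @param x a [HourlyJID-class].
#' @return logical vector of length D.
#' @export
setGeneric("validHours", function(x) standardGeneric("validHours"))

#' @rdname validHours
#' @export
setMethod("validHours", "HourlyJID", function(x) x@valid)

#' Density tensor of an hourly JID
#' @param x a [HourlyJID-class].
#' @return numeric array nSteps x nSteps x D.
#' @export
setGeneric("densityArray", function(x) standardGeneric("densityArray"))

#' @rdname densityArray
#' @export
setMethod("densityArray", "HourlyJID", function(x) x@density)

#' Hour-by-bin matrix view of an hourly JID
#'
#' Returns the D x B matrix whose columns are the per-bin hourly density
#' series in column-major raster order of the grid (bin (r, c) maps to
#' column r + (c - 1) * nSteps) — the layout consumed by the wavelet stage.
#'
#' @param x a [HourlyJID-class].
#' @return numeric matrix D x nSteps^2.
#' @export
setGeneric("densityMatrix", function(x) standardGeneric("densityMatrix"))

#' @rdname densityMatrix
#' @export
setMethod("densityMatrix", "HourlyJID", function(x) {
  n <- x@grid@nSteps
  d <- dim(x@density)[3]
  t(matrix(x@density, n * n, d))
})

#' Power matrix of a periodogram tensor (T x B)
#' @param x a [PeriodogramTensor-class].
#' @return numeric matrix, rows = periods, columns = JID bins (raster order).
#' @export
setGeneric("powerMatrix", function(x) standardGeneric("powerMatrix"))

#' @rdname powerMatrix
#' @export
setMethod("powerMatrix", "PeriodogramTensor", function(x) x@power)

#' 3-D array view of a periodogram tensor (nSteps x nSteps x T)
#' @param x a [PeriodogramTensor-class].
#' @return numeric array.
#' @export
setGeneric("powerArray", function(x) standardGeneric("powerArray"))

#' @rdname powerArray
#' @export
setMethod("powerArray", "PeriodogramTensor", function(x) {
  n <- x@grid@nSteps
  array(t(x@power), dim = c(n, n, nrow(x@power)))
})

#' Meta-rhythm matrix W (periods x rank)
#' @param x a [MetaRhythmSet-class].
#' @return numeric matrix.
#' @export
setGeneric("metaRhythms", function(x) standardGeneric("metaRhythms"))

#' @rdname metaRhythms
#' @export
setMethod("metaRhythms", "MetaRhythmSet", function(x) x@W)

#' Meta-behavior matrix H (rank x JID bins)
#' @param x a [MetaRhythmSet-class].
#' @return numeric matrix.
#' @export
setGeneric("metaBehaviors", function(x) standardGeneric("metaBehaviors"))

#' @rdname metaBehaviors
#' @export
setMethod("metaBehaviors", "MetaRhythmSet", function(x) x@H)

#' Cluster sizes (bins per retained cluster)
#' @param x a [ClusterSet-class].
#' @return integer vector.
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname clusterSizes
#' @export
setMethod("clusterSizes", "ClusterSet", function(x) x@sizes)

#' Family-wise significance flags per cluster
#' @param x a [ClusterSet-class].
#' @return logical vector.
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @rdname isSignificant
#' @export
setMethod("isSignificant", "ClusterSet", function(x) x@significant)

#' Cluster labels (T x B integer matrix, 0 = background)
#' @param x a [ClusterSet-class].
#' @return integer matrix.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ClusterSet", function(x) x@labels)

# ---- show methods ---------------------------------------------------------

setMethod("show", "SubjectConfig", function(object) {
  cat("SubjectConfig:", object@durationDays, "days,",
      nrow(object@rhythms), "injected rhythm(s),",
      nrow(object@gaps), "gap(s), seed", object@seed, "\n")
  cat("  ITI mixture: fast N(", object@fastMean, ",", object@fastSd,
      ") / slow N(", object@slowMean, ",", object@slowSd,
      ") log10(ms), fast weight", object@fastWeight, "\n")
  if (nrow(object@rhythms)) {
    cat("  rhythms:\n")
    print(object@rhythms, row.names = FALSE)
  }
  invisible(NULL)
})

setMethod("show", "TouchEventStream", function(object) {
  ev <- object@events
  nt <- sum(ev$type == "touch")
  cat("TouchEventStream", object@subjectId, ":", nrow(ev), "events (",
      nt, "touches,", sum(ev$type == "screen_on"), "sessions )\n")
  if (nrow(ev)) {
    span <- diff(range(ev$timestampMs)) / 86400e3
    cat("  span:", round(span, 2), "days\n")
  }
  invisible(NULL)
})

setMethod("show", "JIDGrid", function(object) {
  cat("JIDGrid: [", object@axisMin, ",", object@axisMax, "] log10(ms),",
      object@nSteps, "steps/dim (", object@nSteps^2, "bins )\n")
  invisible(NULL)
})

setMethod("show", "HourlyJID", function(object) {
  d <- dim(object@density)
  cat("HourlyJID:", d[1], "x", d[2], "x", d[3], "(bins x bins x hours),",
      sum(object@valid), "valid hours\n")
  invisible(NULL)
})

setMethod("show", "PeriodGrid", function(object) {
  p <- object@periods
  cat("PeriodGrid:", length(p), "periods,",
      object@voicesPerOctave, "voices/octave, range (",
      round(object@periodMin, 3), ",", round(object@periodMax, 1), "] h\n")
  invisible(NULL)
})

setMethod("show", "PeriodogramTensor", function(object) {
  cat("PeriodogramTensor (", object@kind, "):",
      nrow(object@power), "periods x", ncol(object@power), "bins;",
      sum(!is.finite(object@power[, 1])), "unusable period(s)\n")
  invisible(NULL)
})

setMethod("show", "BootstrapEnsemble", function(object) {
  d <- dim(object@power)
  cat("BootstrapEnsemble:", d[3], "bootstraps,", d[1], "periods x",
      d[2], "bins, block", object@blockHours, "h\n")
  invisible(NULL)
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", length(object@sizes), "cluster(s) >=",
      object@minSize, "bins;", sum(object@significant),
      "family-wise significant (threshold", object@fwThreshold, ")\n")
  invisible(NULL)
})

setMethod("show", "MetaRhythmSet", function(object) {
  cat("MetaRhythmSet: rank", object@rank, ",",
      nrow(object@W), "periods, stability",
      round(object@stability, 3), "\n")
  invisible(NULL)
})

setMethod("show", "RhythmClusterSet", function(object) {
  cat("RhythmClusterSet:", object@k, "clusters over",
      nrow(object@assignments), "meta-rhythms\n")
  pk <- round(object@peakPeriod, 1)
  cat("  peak periods (days):", paste(pk, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "CoherenceResult", function(object) {
  cat("CoherenceResult: band [", object@band[1], ",", object@band[2],
      "] days,", nrow(object@pairs), "pairs,",
      sum(object@pairs$significant), "significant\n")
  invisible(NULL)
})
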