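# Base-graphics views of the main containers.

#' Image of one hour's (or an aggregated) JID
#'
#' @param jid an [HourlyJID-class].
#' @param hour index along the hour axis, or NULL to show the mean over
#'   valid hours.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plotJID <- function(jid, hour = NULL, ...) {
  bc <- binCenters(jid@grid)
  m <- if (is.null(hour)) {
    v <- which(jid@valid)
    apply(jid@density[, , v, drop = FALSE], c(1, 2), mean)
  } else jid@density[, , hour]
  graphics::image(bc, bc, m, xlab = "log10 ITI k (ms)",
                  ylab = "log10 ITI k+1 (ms)", ...)
  invisible(m)
}

#' Periodogram of one JID bin
#'
#' @param pt a [PeriodogramTensor-class].
#' @param row,col grid coordinates of the bin.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the power vector.
#' @export
plotBinPeriodogram <- function(pt, row, col, ...) {
  n <- as.integer(pt@grid@nSteps)
  p <- pt@power[, row + (col - 1L) * n]
  d <- pt@periodGrid@periods / 24
  graphics::plot(d, p, type = "l", log = "x", xlab = "period (days)",
                 ylab = if (pt@kind == "raw") "power" else "power index",
                 ...)
  invisible(p)
}

#' Meta-rhythm curves of a factorization
#'
#' @param mrs a [MetaRhythmSet-class].
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the W matrix.
#' @export
plotMetaRhythms <- function(mrs, ...) {
  graphics::matplot(mrs@periods / 24, mrs@W, type = "l", log = "x",
                    xlab = "period (days)", ylab = "meta-rhythm (unit max)",
                    ...)
  invisible(mrs@W)
}

#' Mean curves of the rhythm families
#'
#' @param rcs a [RhythmClusterSet-class].
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the cluster-mean matrix.
#' @export
plotRhythmFamilies <- function(rcs, ...) {
  graphics::matplot(rcs@periods / 24, rcs@clusterMeans, type = "l",
                    log = "x", xlab = "period (days)",
                    ylab = "mean z-scored meta-rhythm", ...)
  invisible(rcs@clusterMeans)
}
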