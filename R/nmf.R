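# Non-negative matrix factorization of period-sliced periodograms.
#
# The adjusted periodogram tensor is sliced to a multiday band, reshaped to
# T' x B, shifted non-negative, and decomposed as W H with W >= 0, H >= 0:
# W's columns are meta-rhythms (periodogram shapes), H's rows the matching
# meta-behaviors (loadings over JID bins). Rank is selected by masked
# cross-validation; stability is handled by the multi-restart "star"
# procedure that keeps the run with the highest median pairwise similarity.

#' Slice and reshape an adjusted periodogram tensor
#'
#' Retains periods in \[pMinDays, pMaxDays\] (usable, i.e. non-NaN, rows
#' only), reshapes to T' x B with columns in column-major raster order of
#' the JID grid, and subtracts the global minimum so all entries are
#' non-negative.
#'
#' @param adjusted an adjusted [PeriodogramTensor-class].
#' @param pMinDays,pMaxDays period band in days.
#' @return a [RhythmMatrix-class].
#' @export
sliceReshape <- function(adjusted, pMinDays = 2.2, pMaxDays = 27.7) {
  ph <- adjusted@periodGrid@periods
  sel <- which(ph >= pMinDays * 24 & ph <= pMaxDays * 24 &
                 is.finite(adjusted@power[, 1]))
  if (!length(sel)) stop("empty period slice")
  M <- adjusted@power[sel, , drop = FALSE]
  shift <- min(M)
  new("RhythmMatrix", values = M - shift, periods = ph[sel],
      shift = shift, nSteps = adjusted@grid@nSteps)
}

# Non-negative double SVD initialization (NNDSVDa variant: zeros filled
# with the matrix mean). Deterministic; pulls multiplicative updates out of
# the local minima random starts often hit at the true rank.
.nndsvdInit <- function(A, rank) {
  s <- svd(A, nu = rank, nv = rank)
  m <- nrow(A); n <- ncol(A)
  W <- matrix(0, m, rank); H <- matrix(0, rank, n)
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  for (j in seq_len(rank)[-1]) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nupvp <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nunvn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (nupvp >= nunvn && nupvp > 0) {
      W[, j] <- sqrt(s$d[j] * nupvp) * up / sqrt(sum(up^2))
      H[j, ] <- sqrt(s$d[j] * nupvp) * vp / sqrt(sum(vp^2))
    } else if (nunvn > 0) {
      W[, j] <- sqrt(s$d[j] * nunvn) * un / sqrt(sum(un^2))
      H[j, ] <- sqrt(s$d[j] * nunvn) * vn / sqrt(sum(vn^2))
    }
  }
  fill <- mean(A)
  W[W <= 0] <- fill / rank
  H[H <= 0] <- fill / rank
  list(W = W, H = H)
}

# Weighted (masked) NNMF by multiplicative updates minimizing
# || mask * (A - W H) ||_F^2. mask = NULL means all entries observed.
.nmfFit <- function(A, rank, mask = NULL, maxIter = 200, tol = 1e-5,
                    init = c("random", "nndsvd")) {
  init <- match.arg(init)
  m <- nrow(A); n <- ncol(A)
  eps <- 1e-12
  if (init == "nndsvd") {
    ini <- .nndsvdInit(if (is.null(mask)) A else mask * A, rank)
    W <- ini$W; H <- ini$H
  } else {
    W <- matrix(stats::runif(m * rank, 0.1, 1), m, rank) * sqrt(mean(A) / rank)
    H <- matrix(stats::runif(rank * n, 0.1, 1), rank, n) * sqrt(mean(A) / rank)
  }
  if (is.null(mask)) {
    MA <- A
    prev <- Inf
    for (it in seq_len(maxIter)) {
      WH <- W %*% H
      H <- H * (crossprod(W, A) / (crossprod(W, WH) + eps))
      WH <- W %*% H
      W <- W * (tcrossprod(A, H) / (tcrossprod(WH, H) + eps))
      if (it %% 10 == 0) {
        err <- sqrt(mean((A - W %*% H)^2))
        if (is.finite(prev) && prev - err < tol * max(err, eps)) break
        prev <- err
      }
    }
  } else {
    MA <- mask * A
    prev <- Inf
    for (it in seq_len(maxIter)) {
      WH <- mask * (W %*% H)
      H <- H * (crossprod(W, MA) / (crossprod(W, WH) + eps))
      WH <- mask * (W %*% H)
      W <- W * (tcrossprod(MA, H) / (tcrossprod(WH, H) + eps))
      if (it %% 10 == 0) {
        R <- mask * (A - W %*% H)
        err <- sqrt(sum(R^2) / max(sum(mask), 1))
        if (is.finite(prev) && prev - err < tol * max(err, eps)) break
        prev <- err
      }
    }
  }
  list(W = W, H = H, rmse = sqrt(mean((A - W %*% H)^2)))
}

#' Rank selection by masked cross-validation
#'
#' Per repetition, a random \code{maskFrac} of entries is held out, the
#' factorization is fit on the remaining entries (zero weight on held-out
#' cells), and the test error is the RMSE on the held-out entries. The
#' same holdout is reused across candidate ranks within a repetition
#' (paired comparison). The optimal rank minimizes the mean test error;
#' ties break toward the smallest rank.
#'
#' @param M a [RhythmMatrix-class] or non-negative matrix.
#' @param ranks candidate ranks (default 3..15).
#' @param maskFrac fraction of entries held out per repetition.
#' @param reps repetitions (>= 2).
#' @param seed RNG seed.
#' @param maxIter multiplicative-update iterations per fit.
#' @return list: \code{rank} (selected), \code{cvCurve} data.frame
#'   (rank, meanTestError).
#' @export
selectRank <- function(M, ranks = 3:15, maskFrac = 0.10, reps = 100,
                       seed = 1L, maxIter = 100) {
  A <- if (is(M, "RhythmMatrix")) M@values else M
  if (reps < 2) stop("need at least 2 repetitions")
  if (any(A < 0)) stop("matrix must be non-negative")
  set.seed(seed)
  nEntry <- length(A)
  nMask <- max(1L, round(maskFrac * nEntry))
  err <- matrix(NA_real_, reps, length(ranks))
  for (r in seq_len(reps)) {
    hold <- sample.int(nEntry, nMask)
    mask <- matrix(1, nrow(A), ncol(A))
    mask[hold] <- 0
    for (j in seq_along(ranks)) {
      fit <- .nmfFit(A, ranks[j], mask = mask, maxIter = maxIter,
                     init = "nndsvd")
      R <- (A - fit$W %*% fit$H)[hold]
      err[r, j] <- sqrt(mean(R^2))
    }
  }
  meanErr <- colMeans(err)
  best <- ranks[which.min(meanErr)]   # which.min takes the first = smallest rank
  list(rank = best,
       cvCurve = data.frame(rank = ranks, meanTestError = meanErr))
}

#' Similarity of two decompositions
#'
#' Pearson correlations between all pairs of meta-rhythm columns;
#' zero-variance columns correlate as 0. \code{"matched"} (default)
#' greedily pairs components by descending correlation and averages the
#' matched values — symmetric, permutation-invariant, and penalizing lost
#' components. \code{"max"} averages, over the columns of \code{Wa}, the
#' maximum correlation against \code{Wb}'s columns (not symmetric).
#'
#' @param Wa,Wb numeric matrices with equal row counts.
#' @param method \code{"matched"} or \code{"max"}.
#' @return scalar in \[-1, 1\].
#' @export
decompositionSimilarity <- function(Wa, Wb, method = c("matched", "max")) {
  method <- match.arg(method)
  stopifnot(nrow(Wa) == nrow(Wb))
  sda <- apply(Wa, 2, stats::sd)
  sdb <- apply(Wb, 2, stats::sd)
  C <- matrix(0, ncol(Wa), ncol(Wb))
  oka <- sda > 0; okb <- sdb > 0
  if (any(oka) && any(okb))
    C[oka, okb] <- stats::cor(Wa[, oka, drop = FALSE], Wb[, okb, drop = FALSE])
  C[!is.finite(C)] <- 0
  if (method == "max") return(mean(apply(C, 1, max)))
  k <- min(dim(C))
  vals <- numeric(k)
  for (i in seq_len(k)) {
    j <- arrayInd(which.max(C), dim(C))
    vals[i] <- C[j[1], j[2]]
    C[j[1], ] <- -Inf
    C[, j[2]] <- -Inf
  }
  mean(vals)
}

#' Stability-selected NNMF ("star" procedure)
#'
#' Repeats the factorization \code{restarts} times from random starts,
#' scores each run by the median of its pairwise similarities (on W) with
#' all other runs, and returns the run with the highest median — the most
#' reproducible decomposition. Meta-rhythm columns are normalized to unit
#' maximum (scale absorbed into H) and ordered by peak period.
#'
#' @param M a [RhythmMatrix-class] or non-negative matrix.
#' @param rank factorization rank (>= 1).
#' @param restarts number of random restarts.
#' @param seed RNG seed.
#' @param maxIter multiplicative-update iterations per fit.
#' @param cvCurve optional cv curve recorded in the result.
#' @return a [MetaRhythmSet-class].
#' @export
starNNMF <- function(M, rank, restarts = 1000, seed = 1L, maxIter = 200,
                     cvCurve = NULL) {
  A <- if (is(M, "RhythmMatrix")) M@values else M
  per <- if (is(M, "RhythmMatrix")) M@periods else seq_len(nrow(A))
  if (all(A == 0)) stop("degenerate all-zero matrix")
  if (rank < 1) stop("rank must be >= 1")
  set.seed(seed)
  runs <- vector("list", restarts)
  for (r in seq_len(restarts))
    runs[[r]] <- .nmfFit(A, rank, maxIter = maxIter)
  if (restarts == 1L) {
    best <- 1L
    score <- 1
  } else {
    S <- matrix(1, restarts, restarts)
    for (i in seq_len(restarts - 1)) {
      for (j in (i + 1):restarts) {
        S[i, j] <- S[j, i] <-
          decompositionSimilarity(runs[[i]]$W, runs[[j]]$W)
      }
    }
    med <- vapply(seq_len(restarts),
                  function(i) stats::median(S[i, -i]), numeric(1))
    best <- which.max(med)
    score <- med[best]
  }
  W <- runs[[best]]$W
  H <- runs[[best]]$H
  # gauge: unit-max meta-rhythms, compensate in H
  mx <- apply(W, 2, max)
  mx[mx <= 0] <- 1
  W <- sweep(W, 2, mx, "/")
  H <- sweep(H, 1, mx, "*")
  o <- order(per[apply(W, 2, which.max)])
  W <- W[, o, drop = FALSE]
  H <- H[o, , drop = FALSE]
  new("MetaRhythmSet", W = W, H = H, rank = rank,
      cvCurve = if (is.null(cvCurve)) data.frame() else cvCurve,
      stability = score, periods = per, seed = as.numeric(seed))
}
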