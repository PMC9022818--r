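## Windowed pairwise Pearson correlation: window bookkeeping, weighted
## correlation, and the FC matrix series.

#' Number of sliding-window positions
#'
#' For a series of `T` volumes, a window of `windowSize` TRs advanced by
#' `stepSize` TRs yields `floor((T - windowSize)/stepSize) + 1` positions;
#' trailing volumes not covered by a final full window are dropped.
#'
#' @param T number of volumes in the series.
#' @param windowSize window length in TRs.
#' @param stepSize moving step in TRs.
#' @return Integer window count.
#' @examples
#' countWindows(300, 17, 1)  # 284
#' @export
countWindows <- function(T, windowSize, stepSize = 1L) {
  if (windowSize < 1L || stepSize < 1L)
    stop("windowSize and stepSize must be at least 1 TR")
  if (windowSize > T)
    stop("window (", windowSize, " TRs) larger than series (", T, " TRs)")
  as.integer(floor((T - windowSize) / stepSize) + 1)
}

#' Weighted Pearson correlation
#'
#' Correlation of two equal-length series under non-negative observation
#' weights, using weighted means and variances. Uniform weights reduce
#' exactly to the ordinary Pearson correlation.
#'
#' @param x,y numeric series of equal length (at least 3).
#' @param w non-negative weights summing to a positive value; default
#'   uniform.
#' @return Correlation in `[-1, 1]`, or `NA` with a warning when either
#'   series is constant under the weights.
#' @export
weightedPearson <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  if (length(y) != n || length(w) != n)
    stop("x, y and w must have equal length")
  if (n < 3)
    stop("at least 3 observations required")
  if (any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with positive sum")
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    warning("constant series under weights: correlation undefined")
    return(NA_real_)
  }
  r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  min(1, max(-1, r))
}

## taper weights for one window, normalized to sum 1
.windowWeights <- function(windowSize, taper, gaussianSigma) {
  if (taper == "rectangular") {
    rep(1 / windowSize, windowSize)
  } else {
    mid <- (windowSize + 1) / 2
    w <- exp(-0.5 * ((seq_len(windowSize) - mid) / gaussianSigma)^2)
    w / sum(w)
  }
}

#' Sliding-window functional connectivity
#'
#' Computes one R x R Pearson correlation matrix per window position.
#' Window `w` covers volumes `[last - windowSize + 1, last]` where
#' `last = windowSize + (w - 1) * stepSize`; setting
#' `windowSize = nTimepoints(ts)` yields the single static (full-duration)
#' correlation matrix. With a Gaussian taper, per-volume weights are drawn
#' from a Gaussian centered at the window midpoint with the given sigma and
#' normalized to sum 1.
#'
#' An ROI that is constant within some window has its correlations in that
#' window flagged missing (`NA`) with a warning; a missing edge is never
#' retained by binarization.
#'
#' @param ts an [ROITimeSeries-class] object with at least 2 ROIs.
#' @param windowSize window length in TRs.
#' @param stepSize moving step in TRs (default 1).
#' @param taper `"rectangular"` (default) or `"gaussian"`.
#' @param gaussianSigma taper width in TRs; default `windowSize/6` so that
#'   +/- 3 sigma spans the window.
#' @return An [FCSeries-class] object.
#' @examples
#' ts <- simulateROITimeSeries(seed = 1)
#' fc <- slidingWindowFC(ts, windowSize = 17)
#' nWindows(fc)  # 284
#' @export
slidingWindowFC <- function(ts, windowSize, stepSize = 1L,
                            taper = c("rectangular", "gaussian"),
                            gaussianSigma = windowSize / 6) {
  taper <- match.arg(taper)
  x <- ts@values
  T <- nrow(x); R <- ncol(x)
  if (R < 2)
    stop("connectivity requires at least 2 ROIs")
  W <- countWindows(T, windowSize, stepSize)
  wts <- .windowWeights(windowSize, taper, gaussianSigma)
  mats <- array(NA_real_, c(R, R, W),
                dimnames = list(ts@roiLabels, ts@roiLabels, NULL))
  lastTR <- integer(W)
  constWarned <- FALSE
  for (w in seq_len(W)) {
    last <- as.integer(windowSize + (w - 1L) * stepSize)
    lastTR[w] <- last
    seg <- x[(last - windowSize + 1L):last, , drop = FALSE]
    mu <- colSums(seg * wts)
    cen <- sweep(seg, 2, mu)
    cov <- crossprod(cen * wts, cen)
    v <- diag(cov)
    rng <- apply(seg, 2, function(col) max(col) - min(col))
    bad <- v <= 0 | rng == 0
    if (any(bad) && !constWarned) {
      warning("ROI constant within a window: edges flagged missing (",
              paste(ts@roiLabels[bad], collapse = ", "), ", window ", w, ")")
      constWarned <- TRUE
    }
    denom <- sqrt(outer(v, v))
    m <- cov / denom
    m[bad, ] <- NA_real_
    m[, bad] <- NA_real_
    m[which(m > 1)] <- 1; m[which(m < -1)] <- -1
    diag(m) <- 1
    mats[, , w] <- (m + t(m)) / 2
  }
  new("FCSeries", matrices = mats, windowLastTR = lastTR,
      windowSize = as.integer(windowSize), stepSize = as.integer(stepSize),
      taper = taper,
      gaussianSigma = if (taper == "gaussian") gaussianSigma else NA_real_,
      tr = ts@tr, roiLabels = ts@roiLabels)
}

#' Persist and restore an FC series
#'
#' The stack of windowed matrices, window mapping and parameters are stored
#' as a single plain-JSON archive (version-tagged), so results are portable
#' and diffable.
#'
#' @param fc an [FCSeries-class] object.
#' @param path output path (`.json`).
#' @return `readFCSeries` returns the restored [FCSeries-class];
#'   `writeFCSeries` returns `path` invisibly.
#' @export
writeFCSeries <- function(fc, path) {
  payload <- list(
    format = "dynfc-fcseries", version = 1L,
    roiLabels = fc@roiLabels, windowSize = fc@windowSize,
    stepSize = fc@stepSize, taper = fc@taper,
    gaussianSigma = fc@gaussianSigma, tr = fc@tr,
    windowLastTR = fc@windowLastTR,
    matrices = fc@matrices)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname writeFCSeries
#' @export
readFCSeries <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "dynfc-fcseries"))
    stop("not an FC-series archive: ", path)
  mats <- p$matrices
  new("FCSeries", matrices = array(as.numeric(mats), dim = dim(mats)),
      windowLastTR = as.integer(p$windowLastTR),
      windowSize = as.integer(p$windowSize),
      stepSize = as.integer(p$stepSize), taper = p$taper,
      gaussianSigma = as.numeric(p$gaussianSigma), tr = as.numeric(p$tr),
      roiLabels = as.character(p$roiLabels))
}
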