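## Band-limiting ROI time series before windowed correlation: zero-phase
## frequency-domain masking, and MODWT wavelet-level selection.

## LA8 (least-asymmetric, length 8) scaling filter; the standard default for
## shift-invariant wavelet filtering of BOLD series. The wavelet filter
## follows by quadrature mirror: h_l = (-1)^l g_{L-1-l}.
.la8ScalingFilter <- c(
  -0.075765714789273330, -0.029635527645998510,
   0.497618667632015450,  0.803738751805916100,
   0.297857795605277360, -0.099219543576847220,
  -0.012603967262037833,  0.032223100604042700)

.qmf <- function(g) {
  L <- length(g)
  rev(g) * (-1)^(seq_len(L) - 1)
}

#' Zero-phase frequency-domain filter
#'
#' Band-limits every column of an ROI time series by masking discrete
#' Fourier coefficients (hard cutoff, zero phase). Cutoffs are given in
#' seconds, i.e. as periods (the inverse of the cutoff frequency):
#' a high-pass filter with `cutoffHighS = 75` passes fluctuations faster
#' than 1/75 Hz; a low-pass with `cutoffLowS = 10` passes fluctuations
#' slower than 1/10 Hz; a band-pass with cutoffs (5, 50) passes
#' 1/50 - 1/5 Hz. The DC component is removed by high- and band-pass and
#' preserved by low-pass.
#'
#' @param ts an [ROITimeSeries-class] object.
#' @param mode `"highpass"`, `"lowpass"` or `"bandpass"`.
#' @param cutoffLowS shorter period bound in seconds (low-pass and
#'   band-pass; the high-frequency edge of the passband).
#' @param cutoffHighS longer period bound in seconds (high-pass and
#'   band-pass; the low-frequency edge of the passband).
#' @return A filtered [ROITimeSeries-class] of identical dimensions.
#' @export
frequencyFilter <- function(ts, mode = c("highpass", "lowpass", "bandpass"),
                            cutoffLowS = NULL, cutoffHighS = NULL) {
  mode <- match.arg(mode)
  x <- ts@values
  T <- nrow(x)
  if (T < 8)
    stop("series too short to filter (T < 8)")
  fs <- 1 / ts@tr
  nyq <- fs / 2
  fLow <- 0        # passband lower frequency edge
  fHigh <- Inf     # passband upper frequency edge
  if (mode %in% c("highpass", "bandpass")) {
    if (is.null(cutoffHighS))
      stop(mode, " requires cutoffHighS (longest passed period, seconds)")
    fLow <- 1 / cutoffHighS
  }
  if (mode %in% c("lowpass", "bandpass")) {
    if (is.null(cutoffLowS))
      stop(mode, " requires cutoffLowS (shortest passed period, seconds)")
    fHigh <- 1 / cutoffLowS
  }
  if (mode == "bandpass" && cutoffHighS <= cutoffLowS)
    stop("bandpass requires cutoffHighS > cutoffLowS (periods in seconds)")
  for (f in c(fLow, fHigh)) {
    if (is.finite(f) && f > nyq)
      stop("cutoff frequency ", signif(f, 4), " Hz beyond Nyquist (",
           signif(nyq, 4), " Hz)")
  }
  freq <- (seq_len(T) - 1) / (T * ts@tr)
  freq <- pmin(freq, fs - freq)          # two-sided spectrum, mirrored
  keep <- freq >= fLow & freq <= fHigh
  if (mode == "lowpass") keep[1] <- TRUE       # preserve DC
  if (mode %in% c("highpass", "bandpass")) keep[1] <- FALSE
  out <- apply(x, 2, function(col) Re(fft(fft(col) * keep, inverse = TRUE)) / T)
  roiTimeSeries(out, tr = ts@tr, roiLabels = ts@roiLabels)
}

## ---------------------------------------------------------------------------
## MODWT (maximal overlap discrete wavelet transform), pyramid algorithm
## ---------------------------------------------------------------------------

## One pyramid stage: circular filtering with the level-j upsampled filter.
## f: length-L filter (already scaled by 1/sqrt(2)); v: length-N input;
## j: level (stride 2^(j-1)).
.modwtStage <- function(f, v, j) {
  N <- length(v)
  stride <- 2L^(j - 1L)
  out <- numeric(N)
  for (l in seq_along(f)) {
    shift <- (l - 1L) * stride
    idx <- ((seq_len(N) - 1L - shift) %% N) + 1L
    out <- out + f[l] * v[idx]
  }
  out
}

## Inverse stage: reconstruct V_{j-1} from (W_j, V_j).
.imodwtStage <- function(h, g, w, v, j) {
  N <- length(v)
  stride <- 2L^(j - 1L)
  out <- numeric(N)
  for (l in seq_along(g)) {
    shift <- (l - 1L) * stride
    idx <- ((seq_len(N) - 1L + shift) %% N) + 1L
    out <- out + h[l] * w[idx] + g[l] * v[idx]
  }
  out
}

#' Maximal overlap discrete wavelet transform
#'
#' Shift-invariant wavelet decomposition of a single series. Boundary
#' handling is by reflection: the series is extended to twice its length by
#' appending its reverse, transformed circularly, and coefficients are
#' truncated back to the original length. The level-`j` wavelet
#' coefficients nominally occupy the frequency band
#' \eqn{[f_s/2^{j+1}, f_s/2^j]}.
#'
#' @param x numeric series.
#' @param levels number of decomposition levels L (requires
#'   `length(x) >= 2^L`).
#' @param filter scaling filter; only the bundled LA8 filter is provided.
#' @param boundary `"reflection"` (default) or `"periodic"`.
#' @return List with `W` (T x L matrix of wavelet coefficients), `V`
#'   (length-T scaling coefficients at level L), plus the filter and
#'   boundary used.
#' @export
modwt <- function(x, levels, filter = .la8ScalingFilter,
                  boundary = c("reflection", "periodic")) {
  boundary <- match.arg(boundary)
  Torig <- length(x)
  if (levels < 1L) stop("levels must be >= 1")
  if (Torig < 2^levels)
    stop("series of length ", Torig, " supports at most ",
         floor(log2(Torig)), " levels")
  if (boundary == "reflection")
    x <- c(x, rev(x))
  g <- filter / sqrt(2)
  h <- .qmf(filter) / sqrt(2)
  N <- length(x)
  W <- matrix(0, N, levels)
  v <- x
  for (j in seq_len(levels)) {
    W[, j] <- .modwtStage(h, v, j)
    v <- .modwtStage(g, v, j)
  }
  list(W = W, V = v, levels = levels, filter = filter, boundary = boundary,
       length = Torig)
}

#' Inverse MODWT
#'
#' Reconstructs a series from MODWT coefficients, optionally using only a
#' subset of detail levels and/or dropping the smooth (scaling) component.
#'
#' @param decomp result of [modwt()].
#' @param keepLevels detail levels to retain (default all).
#' @param keepSmooth retain the level-L scaling (approximation) component?
#' @return Numeric series of the original length.
#' @export
imodwt <- function(decomp, keepLevels = seq_len(decomp$levels),
                   keepSmooth = TRUE) {
  if (length(keepLevels) &&
      (any(keepLevels < 1) || any(keepLevels > decomp$levels)))
    stop("keepLevels must be a subset of 1..", decomp$levels)
  g <- decomp$filter / sqrt(2)
  h <- .qmf(decomp$filter) / sqrt(2)
  N <- nrow(decomp$W)
  v <- if (keepSmooth) decomp$V else numeric(N)
  for (j in rev(seq_len(decomp$levels))) {
    w <- if (j %in% keepLevels) decomp$W[, j] else numeric(N)
    v <- .imodwtStage(h, g, w, v, j)
  }
  v[seq_len(decomp$length)]
}

#' MODWT wavelet-level filter
#'
#' Decomposes each ROI series with an L-level MODWT and reconstructs it
#' from the selected detail levels only. By default the approximation
#' (scaling) band is zeroed, so the output is band-limited to the union of
#' the kept detail bands; set `keepSmooth = TRUE` to retain fluctuations
#' slower than \eqn{f_s/2^{L+1}} as well.
#'
#' @param ts an [ROITimeSeries-class] object.
#' @param levels number of decomposition levels L.
#' @param keepLevels non-empty subset of `1:levels` to reconstruct from.
#' @param keepSmooth retain the approximation band (default `FALSE`).
#' @param boundary boundary rule passed to [modwt()].
#' @return A filtered [ROITimeSeries-class] of identical dimensions.
#' @examples
#' ts <- simulateROITimeSeries(seed = 1)
#' filt <- waveletFilter(ts, levels = 5, keepLevels = 3:5)
#' @export
waveletFilter <- function(ts, levels = 5L, keepLevels = 3:5,
                          keepSmooth = FALSE, boundary = "reflection") {
  if (!length(keepLevels))
    stop("keepLevels must be non-empty")
  if (any(keepLevels < 1) || any(keepLevels > levels))
    stop("keepLevels must be a subset of 1..", levels)
  out <- apply(ts@values, 2, function(col) {
    imodwt(modwt(col, levels = levels, boundary = boundary),
           keepLevels = keepLevels, keepSmooth = keepSmooth)
  })
  roiTimeSeries(out, tr = ts@tr, roiLabels = ts@roiLabels)
}
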