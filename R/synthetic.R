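## Synthetic block-design data with condition-dependent inter-ROI coupling,
## so that every pipeline stage is testable without any imaging data.

#' Simulate block-design ROI time series
#'
#' Generates `nROIs` channels sharing a latent standard-normal signal
#' whose mixing weight depends on the task condition, plus independent
#' Gaussian noise:
#' \deqn{x_{rt} = w_t z_t + \epsilon_{rt}, \quad
#'       \epsilon_{rt} \sim N(0, \sigma^2).}
#' The weight is chosen as \eqn{w = \sigma\sqrt{\rho/(1-\rho)}} so that the
#' population correlation between any two channels, including the noise,
#' equals exactly `rhoTask` during task TRs and `rhoRest` during rest TRs.
#' With `hrfSmoothing = TRUE` the condition switch is passed through the
#' canonical hemodynamic response (globally normalized, clipped to
#' `[0, 1]`), so coupling transitions follow a realistic lag instead of
#' switching instantaneously.
#'
#' The default design emulates a 5 x 30 s task / 5 x 30 s rest block
#' paradigm at TR = 1 s (300 volumes).
#'
#' @param nROIs number of channels (default 10).
#' @param design a [TaskDesign-class]; default
#'   `taskDesign("0 1 0 1 0 1 0 1 0 1", 30, tr = 1)`.
#' @param rhoTask,rhoRest target inter-ROI coupling per condition
#'   (`|rho| < 1`; defaults 0.6 and 0.2).
#' @param noiseSD channel noise standard deviation (default 1).
#' @param hrfSmoothing smooth the coupling switch with the canonical HRF
#'   (default `TRUE`).
#' @param seed RNG seed; the series is bit-identical for a fixed seed.
#' @return An [ROITimeSeries-class] with `sum(durations)` rows.
#' @examples
#' ts <- simulateROITimeSeries(seed = 1)
#' dim(values(ts))  # 300 x 10
#' @export
simulateROITimeSeries <- function(nROIs = 10L,
                                  design = taskDesign("0 1 0 1 0 1 0 1 0 1",
                                                      30, tr = 1),
                                  rhoTask = 0.6, rhoRest = 0.2,
                                  noiseSD = 1, hrfSmoothing = TRUE,
                                  seed = 1L) {
  if (abs(rhoTask) >= 1 || abs(rhoRest) >= 1)
    stop("coupling must satisfy |rho| < 1")
  if (noiseSD <= 0)
    stop("noiseSD must be positive")
  box <- designBoxcar(design)
  T <- length(box)
  state <- if (hrfSmoothing) {
    s <- activationCurve(design, normalization = "global")@values
    pmin(pmax(s, 0), 1)
  } else {
    as.numeric(box)
  }
  ## per-TR coupling target and latent weight (see formula above)
  rho <- rhoRest + (rhoTask - rhoRest) * state
  wt <- sign(rho) * noiseSD * sqrt(abs(rho) / (1 - abs(rho)))
  x <- .withSeed(seed, {
    z <- rnorm(T)
    eps <- matrix(rnorm(T * nROIs, sd = noiseSD), T, nROIs)
    wt * z + eps
  })
  roiTimeSeries(x, tr = design@tr,
                roiLabels = paste0("roi", seq_len(nROIs)))
}

#' Simulate a 4D volume carrying ROI signals
#'
#' Paints each channel of a simulated (or supplied) ROI time series into
#' the voxels of the corresponding ROI and adds independent voxel noise.
#' With `voxelNoiseSD = 0`, [extractROITimeSeries()] recovers the
#' generating series exactly.
#'
#' @param ts an [ROITimeSeries-class] with one column per ROI.
#' @param rois an [ROIDefinition-class]; ROIs must not overlap.
#' @param dims 3D grid dimensions.
#' @param voxelSize voxel edge lengths in mm (default 2 mm isotropic).
#' @param voxelNoiseSD per-voxel noise standard deviation (default 0).
#' @param seed RNG seed for the voxel noise.
#' @return A [VolumeSeries-class] object.
#' @export
simulateVolume <- function(ts, rois, dims = c(10L, 10L, 10L),
                           voxelSize = c(2, 2, 2), voxelNoiseSD = 0,
                           seed = 1L) {
  affine <- diag(c(voxelSize, 1))
  T <- nrow(ts@values)
  vol <- new("VolumeSeries",
             data = array(0, c(dims, T)), voxelSize = voxelSize,
             tr = ts@tr, affine = affine)
  voxels <- .resolveROIs(vol, rois)
  if (length(voxels) != ncol(ts@values))
    stop("one ROI per time-series column required")
  all <- unlist(voxels)
  if (anyDuplicated(all))
    stop("ROIs overlap on the simulation grid")
  nvox <- prod(dims)
  flat <- matrix(0, nvox, T)
  for (r in seq_along(voxels))
    flat[voxels[[r]], ] <- rep(ts@values[, r], each = length(voxels[[r]]))
  if (voxelNoiseSD > 0)
    flat <- flat + .withSeed(seed,
      matrix(rnorm(nvox * T, sd = voxelNoiseSD), nvox, T))
  vol@data <- array(flat, c(dims, T))
  vol
}
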