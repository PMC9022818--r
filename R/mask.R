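## Temporal inclusive mask for block designs: estimated-activation
## thresholding, condition-coverage thresholding, AND combination, and
## manual masks.
##
## Alignment convention (fixed once, see the methods vignette): the two
## component masks are defined per time point; window w (covering volumes
## [first, first + windowSize - 1]) reads the mask at its representative
## time point, by default the window's first volume. Coverage at a time
## point is by default the condition fraction of the windowSize-TR
## neighborhood centered on it. Under these defaults the printed worked
## example (5 x 30 s task / 5 x 30 s rest at TR = 1 s, window 17, step 1,
## activation threshold 0.8, coverage 80%) selects exactly 79 windows.

#' Expand a block design into a per-TR boxcar
#'
#' @param design a [TaskDesign-class] object.
#' @return Integer 0/1 vector of length `sum(durations)`.
#' @examples
#' designBoxcar(taskDesign("0 1", "2 3"))  # 0 0 1 1 1
#' @export
designBoxcar <- function(design) {
  rep(design@condition, design@durations)
}

#' Canonical hemodynamic response function
#'
#' Double-gamma difference: a peak gamma density minus an undershoot gamma
#' density scaled by a ratio. Defaults are the canonical parameters (peak
#' delay 6 s, undershoot delay 16 s, unit dispersions, peak:undershoot
#' ratio 6, 32 s duration).
#'
#' @param t time in seconds (vectorized), `t >= 0`.
#' @param peakDelay,undershootDelay gamma shape parameters (delays in s for
#'   unit dispersion).
#' @param peakDispersion,undershootDispersion gamma scale parameters.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return HRF amplitude at `t` (arbitrary units).
#' @export
canonicalHRF <- function(t, peakDelay = 6, undershootDelay = 16,
                         peakDispersion = 1, undershootDispersion = 1,
                         ratio = 6) {
  dgamma(t, shape = peakDelay / peakDispersion, scale = peakDispersion) -
    dgamma(t, shape = undershootDelay / undershootDispersion,
           scale = undershootDispersion) / ratio
}

#' Estimated activation curve of a block design
#'
#' Convolves the design boxcar with the canonical HRF and samples the
#' result at each TR. The convolution is carried out on a fine grid
#' (`tr/oversampling` seconds) so the sampled curve approximates the
#' continuous-time response at the end of each TR bin. Normalization modes:
#' `"global"` divides by the curve's own maximum (values in `[.., 1]`, 1 at
#' the strongest response); `"single-event"` divides by the peak response
#' to a single one-TR stimulus, so sustained blocks may exceed 1.
#'
#' @param design a [TaskDesign-class] object.
#' @param normalization `"global"` (default) or `"single-event"`.
#' @param oversampling fine-grid subdivisions per TR (default 16).
#' @param hrfDuration HRF support in seconds (default 32).
#' @param ... further parameters passed to [canonicalHRF()].
#' @return An [ActivationCurve-class] of length `sum(durations)`.
#' @export
activationCurve <- function(design, normalization = c("global", "single-event"),
                            oversampling = 16L, hrfDuration = 32, ...) {
  normalization <- match.arg(normalization)
  box <- designBoxcar(design)
  dt <- design@tr / oversampling
  h <- canonicalHRF(seq(0, hrfDuration, by = dt), ...) * dt
  up <- rep(box, each = oversampling)
  cv <- convolve(up, rev(h), type = "open")[seq_along(up)]
  curve <- cv[seq(oversampling, length(up), by = oversampling)]
  denom <- switch(normalization,
    global = max(curve),
    `single-event` = {
      ## peak of the TR-sampled response to a single one-TR stimulus
      evUp <- c(rep(1, oversampling),
                rep(0, oversampling * ceiling(2 * hrfDuration / design@tr)))
      ev <- convolve(evUp, rev(h), type = "open")[seq_along(evUp)]
      max(ev[seq(oversampling, length(evUp), by = oversampling)])
    })
  if (denom <= 0) {
    curve <- curve * 0      # all-rest design: identically zero curve
  } else {
    curve <- curve / denom
  }
  new("ActivationCurve", values = curve, normalization = normalization,
      tr = design@tr)
}

## representative time point of each window under a convention
.windowRepTR <- function(fc, at = c("first", "center", "last")) {
  at <- match.arg(at)
  last <- fc@windowLastTR
  switch(at,
    first = last - fc@windowSize + 1L,
    center = last - as.integer((fc@windowSize - 1) %/% 2),
    last = last)
}

#' Activation-level temporal mask
#'
#' Selects the windows whose representative time point has an estimated
#' activation magnitude above `threshold`.
#'
#' @param curve an [ActivationCurve-class] for the same run.
#' @param fc the [FCSeries-class] the mask will address.
#' @param threshold activation threshold in `[0, 1]` (default 0.8).
#' @param at window-representative convention: `"first"` (default,
#'   calibrated), `"center"` or `"last"`.
#' @return A [TemporalMask-class] with one entry per window.
#' @export
activationMask <- function(curve, fc, threshold = 0.8, at = "first") {
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  if (length(curve@values) < max(fc@windowLastTR))
    stop("activation curve (", length(curve@values),
         " TRs) shorter than the windowed series")
  sel <- curve@values[.windowRepTR(fc, at)] > threshold
  new("TemporalMask", selected = as.logical(sel), source = "activation")
}

#' Condition-coverage temporal mask
#'
#' Selects the windows whose representative time point has at least `pct`
#' percent of its associated window under the chosen condition. With
#' `neighborhood = "centered"` (default, calibrated) the associated window
#' is the `windowSize`-TR span centered on the time point, with
#' out-of-range TRs counting as not under the condition; with
#' `neighborhood = "window"` it is the FC window itself.
#'
#' @param design a [TaskDesign-class] for the same run.
#' @param fc the [FCSeries-class] the mask will address.
#' @param condition condition to cover: 1 = task (default), 0 = rest.
#' @param pct coverage threshold in percent, `0 < pct <= 100` (default 80).
#' @param at window-representative convention (see [activationMask()]).
#' @param neighborhood `"centered"` (default) or `"window"`.
#' @return A [TemporalMask-class] with one entry per window.
#' @export
coverageMask <- function(design, fc, condition = 1L, pct = 80, at = "first",
                         neighborhood = c("centered", "window")) {
  neighborhood <- match.arg(neighborhood)
  if (pct <= 0 || pct > 100)
    stop("pct must lie in (0, 100]")
  box <- designBoxcar(design)
  T <- length(box)
  if (T < max(fc@windowLastTR))
    stop("design (", T, " TRs) shorter than the windowed series")
  ws <- fc@windowSize
  hit <- as.integer(box == condition)
  sel <- if (neighborhood == "window") {
    vapply(seq_len(nWindows(fc)), function(w) {
      last <- fc@windowLastTR[w]
      sum(hit[(last - ws + 1L):last]) / ws >= pct / 100
    }, logical(1))
  } else {
    lo <- (ws - 1L) %/% 2L
    rep_tr <- .windowRepTR(fc, at)
    vapply(rep_tr, function(t) {
      span <- max(1L, t - lo):min(T, t - lo + ws - 1L)
      sum(hit[span]) / ws >= pct / 100   # truncated TRs count against
    }, logical(1))
  }
  new("TemporalMask", selected = sel, source = "coverage")
}

#' Combine temporal masks by logical AND
#'
#' @param a,b [TemporalMask-class] objects of equal length.
#' @return A [TemporalMask-class] with `source = "both"`.
#' @export
combineMasks <- function(a, b) {
  if (length(a@selected) != length(b@selected))
    stop("masks address different window counts (", length(a@selected),
         " vs ", length(b@selected), ")")
  new("TemporalMask", selected = a@selected & b@selected, source = "both")
}

#' Manually defined temporal mask
#'
#' @param indices window indices to select (subset of `1:W`).
#' @param W total number of windows.
#' @return A [TemporalMask-class] with `source = "manual"`.
#' @export
manualMask <- function(indices, W) {
  indices <- as.integer(indices)
  if (length(indices) && (min(indices) < 1L || max(indices) > W))
    stop("window indices out of range 1..", W)
  sel <- logical(W)
  sel[indices] <- TRUE
  new("TemporalMask", selected = sel, source = "manual")
}

#' Task-related temporal mask of a windowed series
#'
#' Convenience wrapper building the activation mask, the coverage mask, or
#' their AND combination for a block design, under the package's calibrated
#' alignment defaults.
#'
#' @param design a [TaskDesign-class].
#' @param fc the [FCSeries-class] to mask.
#' @param activationThreshold activation threshold (default 0.8); `NA`
#'   disables the activation component.
#' @param coveragePct coverage threshold in percent (default 80); `NA`
#'   disables the coverage component.
#' @param condition covered condition (default task, 1).
#' @param normalization activation-curve normalization (default
#'   `"global"`).
#' @param at window-representative convention (default `"first"`).
#' @param neighborhood coverage neighborhood (default `"centered"`).
#' @return A [TemporalMask-class].
#' @examples
#' ts <- simulateROITimeSeries(seed = 1)
#' fc <- slidingWindowFC(ts, windowSize = 17)
#' mask <- taskMask(taskDesign("0 1 0 1 0 1 0 1 0 1", 30), fc)
#' sum(selectedWindows(mask))  # 79
#' @export
taskMask <- function(design, fc, activationThreshold = 0.8, coveragePct = 80,
                     condition = 1L, normalization = "global", at = "first",
                     neighborhood = "centered") {
  useAct <- !is.na(activationThreshold)
  useCov <- !is.na(coveragePct)
  if (!useAct && !useCov)
    stop("at least one of activationThreshold, coveragePct required")
  act <- if (useAct) {
    activationMask(activationCurve(design, normalization = normalization),
                   fc, threshold = activationThreshold, at = at)
  }
  cov <- if (useCov) {
    coverageMask(design, fc, condition = condition, pct = coveragePct,
                 at = at, neighborhood = neighborhood)
  }
  if (useAct && useCov) combineMasks(act, cov) else if (useAct) act else cov
}

#' Write and read a temporal mask file
#'
#' JSON sidecar holding the design vectors, thresholds, convention flags
#' and the boolean mask itself.
#'
#' @param mask a [TemporalMask-class].
#' @param path file path (`.json`).
#' @param design optional [TaskDesign-class] to embed.
#' @param settings optional named list of thresholds/conventions to embed.
#' @return `readTemporalMask` returns the [TemporalMask-class];
#'   `writeTemporalMask` returns `path` invisibly.
#' @export
writeTemporalMask <- function(mask, path, design = NULL, settings = NULL) {
  payload <- list(format = "dynfc-mask", version = 1L,
                  source = mask@source, selected = mask@selected)
  if (!is.null(design))
    payload$design <- list(condition = design@condition,
                           durations = design@durations, tr = design@tr)
  if (!is.null(settings))
    payload$settings <- settings
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTemporalMask
#' @export
readTemporalMask <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "dynfc-mask"))
    stop("not a temporal-mask file: ", path)
  new("TemporalMask", selected = as.logical(p$selected), source = p$source)
}
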