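## Topological stability: variance of a metric over masked windows, group
## averaging, and the paired task-vs-full comparison of variances.

#' Variance of a metric trajectory over masked windows
#'
#' Sample variance (N - 1 denominator) of a per-window metric over the
#' windows selected by a temporal mask; non-finite values are excluded
#' from all moments.
#'
#' @param values numeric metric value per window.
#' @param mask a [TemporalMask-class], logical vector of equal length, or
#'   `NULL` to use every window.
#' @return List with `V` (variance), `mu` (mean) and `N` (windows used).
#' @examples
#' maskedVariance(c(1, 2, 3))  # V = 1
#' @export
maskedVariance <- function(values, mask = NULL) {
  sel <- if (is.null(mask)) rep(TRUE, length(values))
         else if (is(mask, "TemporalMask")) mask@selected
         else as.logical(mask)
  if (length(sel) != length(values))
    stop("mask addresses ", length(sel), " windows but trajectory has ",
         length(values))
  v <- values[sel & is.finite(values)]
  if (length(v) < 2)
    stop("variance undefined: fewer than 2 selected finite windows")
  list(V = var(v), mu = mean(v), N = length(v))
}

#' Group average of metric trajectories
#'
#' Pointwise mean and standard error of the mean across subjects.
#'
#' @param trajectories numeric matrix, one row per subject, one column per
#'   window (a list of equal-length vectors is also accepted).
#' @return List with `mean` and `sem` (both length W) and `nSubjects`.
#' @export
groupAverage <- function(trajectories) {
  if (is.list(trajectories)) {
    len <- lengths(trajectories)
    if (length(unique(len)) != 1L)
      stop("subjects have different window counts: ",
           paste(unique(len), collapse = ", "))
    trajectories <- do.call(rbind, trajectories)
  }
  n <- nrow(trajectories)
  list(mean = colMeans(trajectories),
       sem = apply(trajectories, 2, sd) / sqrt(n),
       nSubjects = n)
}

#' Paired comparison of task-masked and full-duration variances
#'
#' Two-sided paired-sample t-test on per-subject variance pairs. A
#' positive t means the full-duration variance exceeds the task-masked
#' variance, i.e. the property is more stable during the task-related
#' period.
#'
#' @param vTask per-subject variance over the task-masked windows.
#' @param vAll per-subject variance over all windows, same subject order.
#' @return List with `t`, `p`, `df`, `meanDifference` (`vAll - vTask`)
#'   and `degenerate` (`TRUE` when the differences have zero spread, in
#'   which case `t` is `Inf`, `-Inf` or `NaN` rather than an error).
#' @export
pairedVarianceTest <- function(vTask, vAll) {
  if (length(vTask) != length(vAll))
    stop("paired test requires equal subject counts")
  if (length(vTask) < 2)
    stop("paired test requires at least 2 subjects")
  d <- vAll - vTask
  if (sd(d) == 0) {
    ## identical pairs: no evidence of a difference (t = 0, p = 1);
    ## constant non-zero differences: infinite t, flagged degenerate
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = length(d) - 1, meanDifference = 0,
                  degenerate = FALSE))
    warning("zero-spread non-zero differences: degenerate test")
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
                meanDifference = mean(d), degenerate = TRUE))
  }
  tt <- t.test(vAll, vTask, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), meanDifference = mean(d),
       degenerate = FALSE)
}

#' Stability summary for a metric table
#'
#' For every (metric, threshold) pair in a long-format table produced by
#' [metricsOverSeries()], computes the variance over the task-masked
#' windows and over all windows.
#'
#' @param metricTable data.frame `(window, threshold, metric, value)`.
#' @param mask a [TemporalMask-class] addressing the same windows.
#' @return A data.frame `(metric, threshold, Vtask, Vall, muTask, muAll,
#'   Ntask, Nall)`.
#' @export
varianceSummary <- function(metricTable, mask) {
  sel <- if (is(mask, "TemporalMask")) mask@selected else as.logical(mask)
  combos <- unique(metricTable[, c("metric", "threshold")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- metricTable[metricTable$metric == combos$metric[i] &
                       metricTable$threshold == combos$threshold[i], ]
    sub <- sub[order(sub$window), ]
    vt <- maskedVariance(sub$value, sel)
    va <- maskedVariance(sub$value, NULL)
    data.frame(metric = combos$metric[i], threshold = combos$threshold[i],
               Vtask = vt$V, Vall = va$V, muTask = vt$mu, muAll = va$mu,
               Ntask = vt$N, Nall = va$N)
  })
  do.call(rbind, out)
}
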