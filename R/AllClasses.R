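#' @import methods
#' @importFrom stats cor fft sd var t.test dgamma rnorm runif convolve
#' @importFrom stats aggregate setNames
#' @importFrom utils read.table write.table head
NULL

## ---------------------------------------------------------------------------
## Core S4 containers
## ---------------------------------------------------------------------------

#' 4D volume series
#'
#' Container for a 4-dimensional scalar image (x, y, z, t) together with its
#' voxel geometry and sampling interval.
#'
#' @slot data 4D numeric array (x, y, z, t).
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @slot tr repetition time in seconds.
#' @slot affine 4x4 voxel-to-world transform (0-based voxel indices).
#' @exportClass VolumeSeries
setClass("VolumeSeries",
  representation(data = "array", voxelSize = "numeric", tr = "numeric",
                 affine = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 4L)
      msg <- c(msg, "data must be a 4D array")
    if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
      msg <- c(msg, "tr must be a single positive number")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be three positive lengths")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    if (is.null(msg)) TRUE else msg
  })

#' ROI definition
#'
#' A set of regions of interest given either as a label atlas (integer-valued
#' 3D image), a list of binary masks, or spheres in world (mm) coordinates.
#'
#' @slot kind one of `"atlas"`, `"masks"`, `"spheres"`.
#' @slot labels unique ROI identifiers, one per region.
#' @slot atlas integer-valued 3D array (atlas kind) or empty.
#' @slot masks list of logical 3D arrays (mask kind) or empty list.
#' @slot centers R x 3 matrix of sphere centers in mm (sphere kind).
#' @slot radius sphere radius in mm (sphere kind).
#' @slot atlasValues integer atlas value per label (atlas kind).
#' @exportClass ROIDefinition
setClass("ROIDefinition",
  representation(kind = "character", labels = "character", atlas = "array",
                 masks = "list", centers = "matrix", radius = "numeric",
                 atlasValues = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("atlas", "masks", "spheres"))
      msg <- c(msg, "kind must be 'atlas', 'masks' or 'spheres'")
    if (anyDuplicated(object@labels))
      msg <- c(msg, "ROI labels must be unique")
    if (object@kind == "masks" && length(object@masks) != length(object@labels))
      msg <- c(msg, "one mask per label required")
    if (object@kind == "spheres") {
      if (nrow(object@centers) != length(object@labels))
        msg <- c(msg, "one center per label required")
      if (length(object@radius) != 1L || object@radius <= 0)
        msg <- c(msg, "radius must be a single positive length")
    }
    if (is.null(msg)) TRUE else msg
  })

#' ROI time series
#'
#' T x R matrix of per-ROI mean BOLD signal with its repetition time.
#' Columns follow `roiLabels` order.
#'
#' @slot values T x R numeric matrix (rows = time points, columns = ROIs).
#' @slot tr repetition time in seconds.
#' @slot roiLabels R region identifiers.
#' @exportClass ROITimeSeries
setClass("ROITimeSeries",
  representation(values = "matrix", tr = "numeric", roiLabels = "character"),
  validity = function(object) {
    msg <- NULL
    if (anyNA(object@values))
      msg <- c(msg, "time series must not contain missing values")
    if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
      msg <- c(msg, "tr must be a single positive number")
    if (ncol(object@values) != length(object@roiLabels))
      msg <- c(msg, "one label per column required")
    if (anyDuplicated(object@roiLabels))
      msg <- c(msg, "ROI labels must be unique")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an ROITimeSeries
#'
#' @param values T x R numeric matrix, rows are time points.
#' @param tr repetition time in seconds.
#' @param roiLabels optional region labels; defaults to column names or
#'   `roi1..roiR`.
#' @return An [ROITimeSeries-class] object.
#' @export
roiTimeSeries <- function(values, tr, roiLabels = NULL) {
  values <- as.matrix(values)
  if (is.null(roiLabels))
    roiLabels <- colnames(values)
  if (is.null(roiLabels))
    roiLabels <- paste0("roi", seq_len(ncol(values)))
  storage.mode(values) <- "double"
  colnames(values) <- roiLabels
  new("ROITimeSeries", values = values, tr = as.numeric(tr),
      roiLabels = as.character(roiLabels))
}

#' Windowed functional-connectivity series
#'
#' Ordered stack of R x R windowed Pearson correlation matrices with the
#' window-to-time mapping. Window `w` covers the `windowSize` volumes ending
#' at `windowLastTR[w]`.
#'
#' @slot matrices R x R x W array of correlation matrices (unit diagonal).
#' @slot windowLastTR 1-based index of each window's final volume.
#' @slot windowSize window length in TRs.
#' @slot stepSize moving step in TRs.
#' @slot taper `"rectangular"` or `"gaussian"`.
#' @slot gaussianSigma taper width in TRs (Gaussian taper only).
#' @slot tr repetition time in seconds.
#' @slot roiLabels region identifiers.
#' @exportClass FCSeries
setClass("FCSeries",
  representation(matrices = "array", windowLastTR = "integer",
                 windowSize = "integer", stepSize = "integer",
                 taper = "character", gaussianSigma = "numeric",
                 tr = "numeric", roiLabels = "character"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@matrices)
    if (length(d) != 3L || d[1] != d[2])
      msg <- c(msg, "matrices must be an R x R x W array")
    if (length(object@windowLastTR) != d[3])
      msg <- c(msg, "one windowLastTR entry per window required")
    if (d[1] != length(object@roiLabels))
      msg <- c(msg, "one label per node required")
    off <- abs(object@matrices - aperm(object@matrices, c(2, 1, 3)))
    if (any(off > 1e-12, na.rm = TRUE))
      msg <- c(msg, "matrices must be symmetric")
    if (any(abs(object@matrices) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Block task design
#'
#' Per-block condition indicator (0 = rest, 1 = task) and block durations in
#' TRs.
#'
#' @slot condition integer 0/1 per block.
#' @slot durations block lengths in TRs.
#' @slot tr repetition time in seconds.
#' @exportClass TaskDesign
setClass("TaskDesign",
  representation(condition = "integer", durations = "integer", tr = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@condition) != length(object@durations))
      msg <- c(msg, "condition and durations must have equal length")
    if (!all(object@condition %in% c(0L, 1L)))
      msg <- c(msg, "condition entries must be 0 or 1")
    if (any(object@durations < 1L))
      msg <- c(msg, "block durations must be at least 1 TR")
    if (length(object@tr) != 1L || object@tr <= 0)
      msg <- c(msg, "tr must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a block task design
#'
#' @param condition 0/1 vector, one entry per block (0 = rest, 1 = task).
#'   A space-separated string such as `"0 1 0 1"` is also accepted.
#' @param durations block durations in TRs (scalar recycled, vector, or
#'   space-separated string).
#' @param tr repetition time in seconds.
#' @return A [TaskDesign-class] object.
#' @examples
#' taskDesign("0 1 0 1 0 1 0 1 0 1", 30, tr = 1)
#' @export
taskDesign <- function(condition, durations, tr = 1) {
  if (is.character(condition) && length(condition) == 1L)
    condition <- as.numeric(strsplit(trimws(condition), "[ ,]+")[[1]])
  if (is.character(durations) && length(durations) == 1L)
    durations <- as.numeric(strsplit(trimws(durations), "[ ,]+")[[1]])
  if (length(durations) == 1L)
    durations <- rep(durations, length(condition))
  new("TaskDesign", condition = as.integer(condition),
      durations = as.integer(durations), tr = as.numeric(tr))
}

#' Estimated activation curve
#'
#' Per-TR estimate of task-evoked activation, obtained by convolving the
#' design boxcar with the canonical hemodynamic response function.
#'
#' @slot values per-TR activation, normalized per `normalization`.
#' @slot normalization `"global"` (divide by the curve's own maximum) or
#'   `"single-event"` (divide by the peak response to a one-TR stimulus).
#' @slot tr repetition time in seconds.
#' @exportClass ActivationCurve
setClass("ActivationCurve",
  representation(values = "numeric", normalization = "character",
                 tr = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(is.finite(object@values)))
      msg <- c(msg, "activation values must be finite")
    if (object@normalization == "global" &&
        length(object@values) && max(object@values) > 1 + 1e-8)
      msg <- c(msg, "globally normalized curve must not exceed 1")
    if (is.null(msg)) TRUE else msg
  })

#' Temporal inclusive mask
#'
#' Boolean selector over window positions marking task-stimulation-related
#' FC matrices.
#'
#' @slot selected logical, one entry per window.
#' @slot source `"activation"`, `"coverage"`, `"both"` or `"manual"`.
#' @exportClass TemporalMask
setClass("TemporalMask",
  representation(selected = "logical", source = "character"),
  validity = function(object) {
    if (anyNA(object@selected)) "mask entries must be TRUE or FALSE" else TRUE
  })

#' Binary undirected network
#'
#' Symmetric 0/1 adjacency with zero diagonal.
#'
#' @slot adjacency n x n numeric 0/1 matrix.
#' @slot nodeLabels node identifiers.
#' @exportClass BinaryNetwork
setClass("BinaryNetwork",
  representation(adjacency = "matrix", nodeLabels = "character"),
  validity = function(object) {
    msg <- NULL
    a <- object@adjacency
    if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
    if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency entries must be 0 or 1")
    if (!isTRUE(all.equal(a, t(a)))) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(a) != 0)) msg <- c(msg, "diagonal must be zero")
    if (length(object@nodeLabels) != nrow(a))
      msg <- c(msg, "one label per node required")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a binary network from an adjacency matrix
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal (logical matrices
#'   are accepted).
#' @param nodeLabels optional node identifiers.
#' @return A [BinaryNetwork-class] object.
#' @export
binaryNetwork <- function(adjacency, nodeLabels = NULL) {
  a <- as.matrix(adjacency) * 1
  if (is.null(nodeLabels))
    nodeLabels <- rownames(a)
  if (is.null(nodeLabels))
    nodeLabels <- paste0("n", seq_len(nrow(a)))
  dimnames(a) <- list(nodeLabels, nodeLabels)
  new("BinaryNetwork", adjacency = a, nodeLabels = as.character(nodeLabels))
}

## ---------------------------------------------------------------------------
## Accessors and show methods
## ---------------------------------------------------------------------------

#' Number of time points in a series or volume
#' @param x object
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))
setMethod("nTimepoints", "ROITimeSeries", function(x) nrow(x@values))
setMethod("nTimepoints", "VolumeSeries", function(x) dim(x@data)[4])

#' Number of sliding windows in a series
#' @param x an `FCSeries` or `TemporalMask`
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
setMethod("nWindows", "FCSeries", function(x) dim(x@matrices)[3])
setMethod("nWindows", "TemporalMask", function(x) length(x@selected))

#' Region labels of a container
#' @param x object carrying ROI labels
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
setMethod("roiLabels", "ROITimeSeries", function(x) x@roiLabels)
setMethod("roiLabels", "FCSeries", function(x) x@roiLabels)
setMethod("roiLabels", "ROIDefinition", function(x) x@labels)

#' Repetition time in seconds
#' @param x object carrying a TR
#' @export
setGeneric("trInterval", function(x) standardGeneric("trInterval"))
setMethod("trInterval", "ROITimeSeries", function(x) x@tr)
setMethod("trInterval", "VolumeSeries", function(x) x@tr)
setMethod("trInterval", "FCSeries", function(x) x@tr)
setMethod("trInterval", "TaskDesign", function(x) x@tr)

#' Numeric values held by a container
#' @param x object
#' @export
setGeneric("values", function(x) standardGeneric("values"))
setMethod("values", "ROITimeSeries", function(x) x@values)
setMethod("values", "ActivationCurve", function(x) x@values)

#' Correlation matrix stack of an FC series
#' @param x an `FCSeries`
#' @param w optional window index; if given, that R x R matrix is returned
#' @export
setGeneric("fcMatrices", function(x, w = NULL) standardGeneric("fcMatrices"))
setMethod("fcMatrices", "FCSeries", function(x, w = NULL) {
  if (is.null(w)) x@matrices else x@matrices[, , w]
})

#' Index of each window's final volume
#' @param x an `FCSeries`
#' @export
setGeneric("windowLastTR", function(x) standardGeneric("windowLastTR"))
setMethod("windowLastTR", "FCSeries", function(x) x@windowLastTR)

#' Logical window selector of a temporal mask
#' @param x a `TemporalMask`
#' @export
setGeneric("selectedWindows", function(x) standardGeneric("selectedWindows"))
setMethod("selectedWindows", "TemporalMask", function(x) x@selected)

#' Adjacency matrix of a binary network
#' @param x a `BinaryNetwork`
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
setMethod("adjacency", "BinaryNetwork", function(x) x@adjacency)

setMethod("show", "ROITimeSeries", function(object) {
  cat(sprintf("ROITimeSeries: %d time points x %d ROIs, TR = %g s\n",
              nrow(object@values), ncol(object@values), object@tr))
  cat("  ROIs:", paste(head(object@roiLabels, 6), collapse = ", "),
      if (length(object@roiLabels) > 6) "..." else "", "\n")
})

setMethod("show", "FCSeries", function(object) {
  cat(sprintf(
    "FCSeries: %d windows of %d x %d, window %d TR / step %d TR (%s taper)\n",
    nWindows(object), length(object@roiLabels), length(object@roiLabels),
    object@windowSize, object@stepSize, object@taper))
})

setMethod("show", "TaskDesign", function(object) {
  cat(sprintf("TaskDesign: %d blocks, %d TRs total, TR = %g s\n",
              length(object@condition), sum(object@durations), object@tr))
  cat("  condition:", paste(object@condition, collapse = " "), "\n")
})

setMethod("show", "TemporalMask", function(object) {
  cat(sprintf("TemporalMask (%s): %d of %d windows selected\n",
              object@source, sum(object@selected), length(object@selected)))
})

setMethod("show", "BinaryNetwork", function(object) {
  cat(sprintf("BinaryNetwork: %d nodes, %d edges\n",
              nrow(object@adjacency), sum(object@adjacency) / 2))
})

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeSeries: %d x %d x %d voxels x %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], object@tr))
})

setMethod("show", "ActivationCurve", function(object) {
  cat(sprintf("ActivationCurve: %d TRs, %s normalization, max = %.3f\n",
              length(object@values), object@normalization,
              if (length(object@values)) max(object@values) else NA))
})

## internal: evaluate expr under a temporary seed, leaving the session RNG
## state untouched
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)
  expr
}

## internal: accept BinaryNetwork or plain matrix everywhere
.adj <- function(g) {
  if (is(g, "BinaryNetwork")) g@adjacency
  else {
    a <- as.matrix(g) * 1
    diag(a) <- 0
    a
  }
}
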