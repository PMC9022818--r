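## Reading 4D volumes, resolving ROI geometry, extracting mean time series,
## and round-tripping delimited matrices / result tables.

#' Read a 4D NIfTI volume
#'
#' Reads an uncompressed (`.nii`) or gzip-compressed (`.nii.gz`) NIfTI-1
#' image and returns it with its voxel geometry. The repetition time is
#' taken from the header (`pixdim[4]`) unless overridden.
#'
#' @param path path to a 4D NIfTI file.
#' @param tr optional repetition time in seconds, overriding the header.
#' @return A [VolumeSeries-class] object.
#' @export
readVolume <- function(path, tr = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D image, got ", length(d), " dimensions")
  pd <- RNifti::pixdim(img)
  if (is.null(tr)) {
    tr <- if (length(pd) >= 4) pd[4] else NA_real_
    if (!is.finite(tr) || tr <= 0)
      stop("header carries no usable TR (pixdim[4] = ", tr,
           "); supply tr explicitly")
  }
  new("VolumeSeries", data = array(as.numeric(img), dim = d),
      voxelSize = as.numeric(pd[1:3]), tr = as.numeric(tr),
      affine = structure(RNifti::xform(img), class = "matrix",
                         code = NULL)[1:4, 1:4])
}

#' Write a 4D volume as NIfTI
#'
#' @param vol a [VolumeSeries-class] object.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  img <- RNifti::`qform<-`(img, structure(vol@affine, code = 2L))
  RNifti::pixdim(img) <- c(vol@voxelSize, vol@tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' ROI definitions
#'
#' Constructors for the three supported ROI geometries: a label atlas
#' (integer-valued image, one ROI per non-zero label), a set of binary
#' masks, and spheres given by world-space centers and a common radius.
#'
#' @param atlas integer-valued 3D array or path to a NIfTI label image.
#' @param labels optional ROI identifiers. For `roiAtlas`, defaults to
#'   `label<value>` for each non-zero atlas value (ascending).
#' @param values optional integer atlas values matching `labels`.
#' @param affine optional 4x4 voxel-to-world transform of the atlas grid,
#'   used to check grid agreement with the data volume.
#' @return An [ROIDefinition-class] object.
#' @export
roiAtlas <- function(atlas, labels = NULL, values = NULL, affine = NULL) {
  if (is.character(atlas)) {
    img <- RNifti::readNifti(atlas)
    affine <- structure(RNifti::xform(img), class = "matrix")[1:4, 1:4]
    atlas <- array(as.numeric(img), dim = dim(img))
  }
  if (length(dim(atlas)) != 3L)
    stop("atlas must be a 3D label image")
  if (is.null(values)) {
    values <- sort(unique(as.integer(atlas[atlas != 0])))
    if (!length(values)) stop("atlas contains no non-zero labels")
  }
  if (is.null(labels))
    labels <- paste0("label", values)
  obj <- new("ROIDefinition", kind = "atlas", labels = as.character(labels),
             atlas = atlas, masks = list(), centers = matrix(0, 0, 3),
             radius = NA_real_, atlasValues = as.integer(values))
  attr(obj, "affine") <- affine
  obj
}

#' @rdname roiAtlas
#' @param masks list of logical/0-1 3D arrays, one per ROI.
#' @export
roiMasks <- function(masks, labels = NULL) {
  if (is.null(labels))
    labels <- names(masks)
  if (is.null(labels))
    labels <- paste0("roi", seq_along(masks))
  masks <- lapply(masks, function(m) {
    if (length(dim(m)) != 3L) stop("each mask must be a 3D array")
    m != 0
  })
  new("ROIDefinition", kind = "masks", labels = as.character(labels),
      atlas = array(0, c(0, 0, 0)), masks = masks,
      centers = matrix(0, 0, 3), radius = NA_real_, atlasValues = integer())
}

#' @rdname roiAtlas
#' @param centers R x 3 matrix of sphere centers in mm (world space).
#' @param radius sphere radius in mm; a voxel belongs to a sphere when its
#'   center lies within `radius` (inclusive) of the sphere center.
#' @export
roiSpheres <- function(centers, radius, labels = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3L) stop("centers must be an R x 3 matrix (mm)")
  if (is.null(labels))
    labels <- rownames(centers)
  if (is.null(labels))
    labels <- paste0("roi", seq_len(nrow(centers)))
  new("ROIDefinition", kind = "spheres", labels = as.character(labels),
      atlas = array(0, c(0, 0, 0)), masks = list(), centers = centers,
      radius = as.numeric(radius), atlasValues = integer())
}

## voxel-center world coordinates of every voxel in a grid (0-based indices)
.voxelCenters <- function(dims, affine) {
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1,
                               y = seq_len(dims[2]) - 1,
                               z = seq_len(dims[3]) - 1))
  t(affine %*% t(cbind(idx, 1)))[, 1:3, drop = FALSE]
}

## resolve an ROIDefinition against a volume grid -> list of linear voxel
## index vectors, one per label
.resolveROIs <- function(vol, rois) {
  dims <- dim(vol@data)[1:3]
  nvox <- prod(dims)
  switch(rois@kind,
    atlas = {
      if (!all(dim(rois@atlas) == dims))
        stop("atlas grid does not match data grid (",
             paste(dim(rois@atlas), collapse = "x"), " vs ",
             paste(dims, collapse = "x"), ")")
      aff <- attr(rois, "affine")
      if (!is.null(aff) && max(abs(aff - vol@affine)) > 1e-4)
        stop("atlas and data are not in the same space (affines differ)")
      lapply(seq_along(rois@labels), function(i) {
        v <- which(as.integer(round(rois@atlas)) == rois@atlasValues[i])
        if (!length(v))
          stop("ROI '", rois@labels[i], "' contains no voxels in the atlas")
        v
      })
    },
    masks = lapply(seq_along(rois@labels), function(i) {
      m <- rois@masks[[i]]
      if (!all(dim(m) == dims))
        stop("mask grid for ROI '", rois@labels[i],
             "' does not match data grid")
      v <- which(m)
      if (!length(v))
        stop("ROI '", rois@labels[i], "' contains no voxels")
      v
    }),
    spheres = {
      cen <- .voxelCenters(dims, vol@affine)
      lapply(seq_along(rois@labels), function(i) {
        d2 <- (cen[, 1] - rois@centers[i, 1])^2 +
              (cen[, 2] - rois@centers[i, 2])^2 +
              (cen[, 3] - rois@centers[i, 3])^2
        v <- which(d2 <= rois@radius^2 + 1e-9)
        if (!length(v))
          stop("ROI '", rois@labels[i],
               "' contains no voxels on this grid")
        v
      })
    })
}

#' Extract per-ROI mean time series from a 4D volume
#'
#' For each ROI the unweighted arithmetic mean over its voxels is taken at
#' every time point. The ROI geometry must resolve on the volume grid; no
#' resampling is performed (aligning data and atlas to a common space is an
#' upstream preprocessing step).
#'
#' @param vol a [VolumeSeries-class] object.
#' @param rois an [ROIDefinition-class] object.
#' @return An [ROITimeSeries-class] with one column per ROI.
#' @export
extractROITimeSeries <- function(vol, rois) {
  voxels <- .resolveROIs(vol, rois)
  d <- dim(vol@data)
  flat <- matrix(vol@data, nrow = prod(d[1:3]), ncol = d[4])
  vals <- vapply(voxels, function(v) colMeans(flat[v, , drop = FALSE]),
                 numeric(d[4]))
  roiTimeSeries(vals, tr = vol@tr, roiLabels = rois@labels)
}

#' Read a delimited ROI time-series matrix
#'
#' Rows are time points, columns are ROIs. The delimiter is sniffed from
#' the first line (tab or comma); a non-numeric first row is treated as a
#' header of ROI labels.
#'
#' @param path path to a TSV/CSV file.
#' @param tr repetition time in seconds.
#' @return An [ROITimeSeries-class] object.
#' @export
readMatrixTimeSeries <- function(path, tr) {
  if (!file.exists(path))
    stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  fields <- strsplit(trimws(first), if (sep == "") "[[:space:]]+" else sep)[[1]]
  header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- utils::read.table(path, header = header, sep = sep,
                          check.names = FALSE, colClasses = "numeric")
  m <- as.matrix(df)
  if (!is.numeric(m) || anyNA(m))
    stop("non-numeric cell in time-series table")
  roiTimeSeries(m, tr = tr,
                roiLabels = if (header) colnames(df) else NULL)
}

#' Write an ROI time series as a delimited matrix
#'
#' @param ts an [ROITimeSeries-class] object.
#' @param path output path; `.csv` extension selects comma, otherwise tab.
#' @return `path`, invisibly.
#' @export
writeMatrixTimeSeries <- function(ts, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(ts@values, path, sep = sep, row.names = FALSE,
                     col.names = ts@roiLabels, quote = FALSE)
  invisible(path)
}

#' Write and read result tables
#'
#' Plain TSV with full-precision numbers, so that a write/read round trip
#' reproduces values exactly as printed.
#'
#' @param df a data.frame of results.
#' @param path file path.
#' @return `readResultsTable` returns a data.frame; `writeResultsTable`
#'   returns `path` invisibly.
#' @export
writeResultsTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}
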