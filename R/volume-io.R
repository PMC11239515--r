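# Reading/writing 4D NIfTI series, ROI masks and centerline TSV tables.

#' Construct a VolumeSeries from an array
#'
#' @param data 4D numeric array (x, y, z, t)
#' @param voxelSize voxel edge lengths in mm (default 1.2 x 1.2 x 5, the
#'   in-plane resolution and slice thickness typical of axial cervical-cord
#'   gradient-echo EPI)
#' @param affine 4x4 voxel-to-world matrix; default built from `voxelSize`
#' @param normalized `"raw"` or `"minmax"`
#' @return a [VolumeSeries-class]
#' @export
volumeSeries <- function(data, voxelSize = c(1.2, 1.2, 5),
                         affine = NULL, normalized = "raw") {
  if (is.null(affine)) affine <- diag(c(voxelSize, 1))
  new("VolumeSeries", data = data, voxelSize = as.numeric(voxelSize),
      affine = affine, normalized = normalized)
}

#' Construct an ROI mask
#' @param data 3D array of 0/1 (logical accepted)
#' @param label `"cord"`, `"csf"` or `"other"`
#' @return a [RoiMask-class]
#' @export
roiMask <- function(data, label = "other") {
  storage.mode(data) <- "double"
  new("RoiMask", data = data, label = label)
}

#' Read a 4D NIfTI series
#'
#' @param path path to a `.nii`/`.nii.gz` file containing a 4D image
#' @return a [VolumeSeries-class] with `normalized = "raw"`
#' @export
readVolumeSeries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- structure(as.vector(img), dim = dim(img))
  if (length(dim(arr)) != 4L)
    stop("expected 4D series, got ", length(dim(arr)), "D image: ", path)
  nbad <- sum(!is.finite(arr))
  if (nbad > 0L)
    stop("series contains ", nbad, " non-finite (NaN/Inf) voxel(s): ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  volumeSeries(arr, voxelSize = vox, affine = aff, normalized = "raw")
}

#' Read a 3D NIfTI mask
#' @param path file path
#' @param label ROI label to attach
#' @return a [RoiMask-class]
#' @export
readRoiMask <- function(path, label = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- structure(as.vector(img), dim = dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1L, drop = TRUE]
  if (length(dim(arr)) != 3L) stop("expected 3D mask: ", path)
  roiMask((arr != 0) + 0, label = label)
}

#' Write a series (or mask) as NIfTI
#' @param series a [VolumeSeries-class] or [RoiMask-class]
#' @param path output path (`.nii` or `.nii.gz`)
#' @param affine optional 4x4 affine for masks
#' @return invisibly, the path
#' @export
writeVolumeSeries <- function(series, path, affine = NULL) {
  if (is(series, "VolumeSeries")) {
    arr <- series@data
    aff <- series@affine
  } else if (is(series, "RoiMask")) {
    arr <- series@data
    aff <- if (is.null(affine)) diag(4) else affine
  } else stop("series must be a VolumeSeries or RoiMask")
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("could not write NIfTI to ", path)
  invisible(path)
}

#' Per-volume min-max normalization
#'
#' Maps each volume (time point) independently to [0, 1] via
#' (v - min) / (max - min). A constant volume maps to all zeros. Applying
#' the map to a volume already spanning [0, 1] leaves it unchanged, but a
#' series flagged as normalized is refused outright so the transform cannot
#' be silently compounded.
#'
#' @param series a raw [VolumeSeries-class]
#' @return the normalized series (`normalized = "minmax"`)
#' @export
minmaxNormalize <- function(series) {
  stopifnot(is(series, "VolumeSeries"))
  if (series@normalized != "raw")
    stop("series is already normalized; double normalization is forbidden")
  d <- series@data
  nt <- dim(d)[4]
  for (t in seq_len(nt)) {
    v <- d[, , , t, drop = FALSE]
    lo <- min(v); hi <- max(v)
    d[, , , t] <- if (hi > lo) (v - lo) / (hi - lo) else 0
  }
  initialize(series, data = d, normalized = "minmax")
}

# ---- centerline tables -----------------------------------------------------

#' Write a centerline track as TSV
#'
#' Columns: `slice`, `volume` (both 1-based), `x`, `y` (0-based fractional
#' voxel coordinates) and `outlier_flag` (0/1).
#'
#' @param track a [CenterlineTrack-class]
#' @param path output TSV path
#' @return invisibly, the path
#' @export
writeCenterlineTsv <- function(track, path) {
  stopifnot(is(track, "CenterlineTrack"))
  d <- dim(track@coords)
  df <- expand.grid(slice = seq_len(d[1]), volume = seq_len(d[2]))
  df$x <- as.vector(track@coords[, , 1])
  df$y <- as.vector(track@coords[, , 2])
  df$outlier_flag <- as.integer(as.vector(track@outlier))
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("could not write centerline TSV to ", path)
  invisible(path)
}

#' Read a centerline track from TSV
#' @param path TSV with columns slice, volume, x, y, outlier_flag
#' @return a [CenterlineTrack-class] with `source = "external"`
#' @export
readCenterlineTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path)
  need <- c("slice", "volume", "x", "y", "outlier_flag")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("centerline TSV is missing column(s): ", paste(miss, collapse = ", "))
  nz <- max(df$slice); nt <- max(df$volume)
  coords <- array(NA_real_, c(nz, nt, 2))
  outlier <- matrix(FALSE, nz, nt)
  idx <- cbind(df$slice, df$volume)
  coords[cbind(idx, 1L)] <- df$x
  coords[cbind(idx, 2L)] <- df$y
  outlier[idx] <- df$outlier_flag != 0
  new("CenterlineTrack", coords = coords, outlier = outlier,
      source = "external", repaired = FALSE)
}
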