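#' @import methods
#' @importFrom stats quantile sd rnorm runif median var cor predict
#' @importFrom utils read.delim write.table head tail
#' @useDynLib SpineMoCo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' 4D fMRI volume series
#'
#' Container for an axial 4D time series (x, y, z, t) with its voxel geometry.
#' The first in-plane axis is x (lateral, left-right), the second y
#' (anterior-posterior); voxel indices are 0-based in all coordinate
#' reporting. The `normalized` flag records whether intensities are raw or
#' have been min-max mapped to [0, 1] per volume.
#'
#' @slot data four-dimensional numeric array (x, y, z, t)
#' @slot voxelSize numeric length-3, voxel edge lengths in mm
#' @slot affine 4x4 voxel-to-world matrix
#' @slot normalized `"raw"` or `"minmax"`
#' @export
setClass("VolumeSeries",
  representation(data = "array", voxelSize = "numeric",
                 affine = "matrix", normalized = "character"),
  prototype(voxelSize = c(1, 1, 1), affine = diag(4), normalized = "raw"))

setValidity("VolumeSeries", function(object) {
  d <- object@data
  if (length(dim(d)) != 4L) return("data must be a 4D array (x, y, z, t)")
  if (any(dim(d) < 1L)) return("all four dimensions must be >= 1")
  nbad <- sum(!is.finite(d))
  if (nbad > 0L)
    return(sprintf("data contains %d non-finite voxel(s)", nbad))
  if (!object@normalized %in% c("raw", "minmax"))
    return("normalized must be 'raw' or 'minmax'")
  if (object@normalized == "minmax" &&
      (min(d) < 0 || max(d) > 1 + 1e-12))
    return("minmax-normalized data must lie in [0, 1]")
  if (length(object@voxelSize) != 3L) return("voxelSize must have length 3")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  TRUE
})

#' Binary region-of-interest mask
#'
#' @slot data 3D binary array on the grid of the series it annotates
#' @slot label one of `"cord"`, `"csf"`, `"other"`
#' @export
setClass("RoiMask",
  representation(data = "array", label = "character"),
  prototype(label = "other"))

setValidity("RoiMask", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("mask data must be a 3D array")
  if (!all(d %in% c(0, 1))) return("mask values must be 0 or 1")
  if (!object@label %in% c("cord", "csf", "other"))
    return("label must be 'cord', 'csf' or 'other'")
  TRUE
})

#' Per-slice, per-volume cord centerline track
#'
#' Cord center coordinates, in 0-based fractional voxel units, for every
#' (slice, volume) pair, with outlier flags from the interquartile-range
#' fence step.
#'
#' @slot coords array (nz, nt, 2) of (x, y) centers; NA marks unmeasurable
#' @slot outlier logical matrix (nz, nt)
#' @slot source `"centroid"` or `"external"`
#' @slot repaired logical; TRUE once outliers have been replaced
#' @export
setClass("CenterlineTrack",
  representation(coords = "array", outlier = "matrix",
                 source = "character", repaired = "logical"),
  prototype(source = "centroid", repaired = FALSE))

setValidity("CenterlineTrack", function(object) {
  dc <- dim(object@coords)
  if (length(dc) != 3L || dc[3] != 2L)
    return("coords must be an (nz, nt, 2) array")
  if (!all(dim(object@outlier) == dc[1:2]))
    return("outlier flags must match coords (nz, nt)")
  if (!object@source %in% c("centroid", "external"))
    return("source must be 'centroid' or 'external'")
  if (isTRUE(object@repaired) && any(!is.finite(object@coords)))
    return("repaired track must have finite coords")
  TRUE
})

#' Network architecture preset
#'
#' UNet-style encoder-decoder plan: stride-2 3x3 convolutions down, nearest
#' upsampling plus skip-concatenation and 3x3 convolutions up, optional
#' full-resolution refinement layers, and a final 2-channel flow layer.
#' Two presets are provided: `"drm1"` (larger) and `"drm2"` (compact).
#'
#' @slot preset preset name
#' @slot encoderChannels output widths of the stride-2 encoder convolutions
#' @slot decoderChannels widths of the decoder convolutions
#' @slot refineChannels widths of extra full-resolution convolutions
#' @slot slope leaky-ReLU negative slope
#' @slot batchNorm logical, batch normalization after every conv but the flow
#' @export
setClass("ModelSpec",
  representation(preset = "character", encoderChannels = "numeric",
                 decoderChannels = "numeric", refineChannels = "numeric",
                 slope = "numeric", batchNorm = "logical"))

setValidity("ModelSpec", function(object) {
  if (length(object@encoderChannels) != length(object@decoderChannels))
    return("encoder and decoder depth must match")
  if (length(object@encoderChannels) < 1L) return("need at least one level")
  if (object@slope < 0 || object@slope >= 1) return("slope must be in [0, 1)")
  TRUE
})

#' Trained network weights
#'
#' @slot params list of per-layer parameter arrays
#' @slot spec the [ModelSpec-class] the weights belong to
#' @slot seed initialization seed
#' @export
setClass("ModelWeights",
  representation(params = "list", spec = "ModelSpec", seed = "numeric"))

#' Quality-control report
#'
#' @slot tsnrMap 3D voxelwise temporal SNR map
#' @slot tsnrMean named numeric: mean tSNR globally and per ROI
#' @slot dvarsSeries per-frame DVARS, length nt - 1
#' @slot dvarsMean scalar mean DVARS
#' @slot ccSeries per-volume Pearson correlation to the reference
#' @slot ccMean scalar mean correlation
#' @slot provenance list of free-form provenance fields
#' @export
setClass("QCReport",
  representation(tsnrMap = "array", tsnrMean = "numeric",
                 dvarsSeries = "numeric", dvarsMean = "numeric",
                 ccSeries = "numeric", ccMean = "numeric",
                 provenance = "list"))

setValidity("QCReport", function(object) {
  if (any(object@ccSeries < -1 - 1e-9 | object@ccSeries > 1 + 1e-9))
    return("correlation values must lie in [-1, 1]")
  TRUE
})

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeSeries: %d x %d x %d voxels, %d volumes (%s)\n",
              d[1], d[2], d[3], d[4], object@normalized))
  cat(sprintf("  voxel size: %s mm\n",
              paste(signif(object@voxelSize, 3), collapse = " x ")))
})

setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask '%s': %s, %d voxels set\n", object@label,
              paste(dim(object@data), collapse = " x "), sum(object@data)))
})

setMethod("show", "CenterlineTrack", function(object) {
  d <- dim(object@coords)
  cat(sprintf("CenterlineTrack: %d slices x %d volumes (%s%s), %d outlier(s)\n",
              d[1], d[2], object@source,
              if (object@repaired) ", repaired" else "",
              sum(object@outlier)))
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec '%s': encoder [%s], decoder [%s], refine [%s]\n",
              object@preset,
              paste(object@encoderChannels, collapse = ", "),
              paste(object@decoderChannels, collapse = ", "),
              paste(object@refineChannels, collapse = ", ")))
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n")
  cat("  tSNR mean:", paste(sprintf("%s=%.3f", names(object@tsnrMean),
                                    object@tsnrMean), collapse = ", "), "\n")
  cat(sprintf("  DVARS mean: %.4f over %d frames\n", object@dvarsMean,
              length(object@dvarsSeries)))
  cat(sprintf("  CC to reference: %.4f mean\n", object@ccMean))
})

# ---- accessors -------------------------------------------------------------

#' Extract the voxel data array
#' @param x a VolumeSeries or RoiMask
#' @return the underlying numeric array
#' @export
seriesData <- function(x) {
  stopifnot(is(x, "VolumeSeries"))
  x@data
}

#' @rdname seriesData
#' @export
maskData <- function(x) {
  stopifnot(is(x, "RoiMask"))
  x@data
}

#' Centerline coordinates and outlier flags
#' @param x a CenterlineTrack
#' @return `trackCoords`: (nz, nt, 2) array; `trackOutliers`: logical matrix
#' @export
trackCoords <- function(x) {
  stopifnot(is(x, "CenterlineTrack"))
  x@coords
}

#' @rdname trackCoords
#' @export
trackOutliers <- function(x) {
  stopifnot(is(x, "CenterlineTrack"))
  x@outlier
}
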