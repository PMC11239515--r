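# Centerline realignment preprocessing: track the cord center per slice
# over time, reject implausible points with interquartile-range fences,
# repair them with a cubic B-spline fitted along time, and realign every
# slice-time image by translation (y-only by default, since breathing-driven
# anterior-posterior motion dominates while the shoulders hold x steady).

#' Result of centerline realignment
#'
#' @slot series the realigned [VolumeSeries-class]
#' @slot shifts (nz, nt, 2) applied content shifts (dx, dy) in voxels:
#'   exactly `reference - center` per slice and volume, x zeroed in
#'   `y_only` mode
#' @slot mode `"y_only"` or `"xy"`
#' @export
setClass("RealignmentResult",
  representation(series = "VolumeSeries", shifts = "array",
                 mode = "character"))

setMethod("show", "RealignmentResult", function(object) {
  d <- dim(object@shifts)
  cat(sprintf("RealignmentResult (%s): %d slices x %d volumes, max |shift| %.2f voxels\n",
              object@mode, d[1], d[2], max(abs(object@shifts))))
})

#' Extract the cord centerline from a series
#'
#' For every (slice, volume) the center is the intensity-weighted centroid,
#' taken over the mask when one is supplied, otherwise over the voxels at or
#' above the slice's half-range threshold (midpoint of min and max). Slices
#' where nothing survives (empty mask, all-zero image) are flagged as
#' outliers with NA coordinates, to be repaired rather than raised.
#'
#' @param series a min-max normalized [VolumeSeries-class]
#' @param mask optional cord [RoiMask-class]
#' @return a [CenterlineTrack-class] (`source = "centroid"`)
#' @export
extractCenterline <- function(series, mask = NULL) {
  stopifnot(is(series, "VolumeSeries"))
  if (series@normalized != "minmax")
    stop("series must be min-max normalized before centerline extraction")
  d <- series@data
  dm <- dim(d)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]; nt <- dm[4]
  coords <- array(NA_real_, c(nz, nt, 2))
  outlier <- matrix(FALSE, nz, nt)
  xg <- matrix(0:(nx - 1), nx, ny)
  yg <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)
  for (z in seq_len(nz)) {
    mz <- if (!is.null(mask)) mask@data[, , z] else NULL
    for (t in seq_len(nt)) {
      sl <- d[, , z, t]
      w <- if (!is.null(mz)) {
        sl * mz
      } else {
        thr <- min(sl) + 0.5 * (max(sl) - min(sl))
        sl * (sl >= thr & sl > 0)
      }
      s <- sum(w)
      if (s <= 0) {
        outlier[z, t] <- TRUE
      } else {
        coords[z, t, 1] <- sum(w * xg) / s
        coords[z, t, 2] <- sum(w * yg) / s
      }
    }
  }
  new("CenterlineTrack", coords = coords, outlier = outlier,
      source = if (is.null(mask)) "centroid" else "centroid",
      repaired = FALSE)
}

#' Flag and repair centerline outliers
#'
#' Per slice and per coordinate, entries outside the Tukey fences
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` over time (quartiles by linear
#' interpolation of order statistics) are flagged; flagged and missing
#' entries are replaced by evaluating a degree-3 B-spline fitted along time
#' to the inliers (an interpolating spline when `smoothing = 0`). With
#' fewer than 4 inliers the replacement falls back to the inlier median.
#'
#' @param track a [CenterlineTrack-class] with at least 5 volumes per slice
#' @param smoothing 0 for an interpolating spline (default); a value in
#'   (0, 1] is passed to [stats::smooth.spline()] as `spar`
#' @return the repaired track (`repaired = TRUE`)
#' @export
repairOutliers <- function(track, smoothing = 0) {
  stopifnot(is(track, "CenterlineTrack"))
  coords <- track@coords
  outlier <- track@outlier
  nz <- dim(coords)[1]; nt <- dim(coords)[2]
  if (nt < 5) stop("need at least 5 volumes per slice to repair a track")
  for (z in seq_len(nz)) {
    flagged <- outlier[z, ] | apply(is.na(coords[z, , ]), 1, any)
    for (k in 1:2) {
      v <- coords[z, , k]
      ok <- !is.na(v) & !outlier[z, ]
      if (!any(ok))
        stop("all centerline entries are outliers on slice ", z)
      q <- quantile(v[ok], c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      fence <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
      flagged <- flagged | (!is.na(v) & (v < fence[1] | v > fence[2]))
    }
    if (all(flagged))
      stop("all centerline entries are outliers on slice ", z)
    outlier[z, ] <- flagged
    tin <- which(!flagged)
    for (k in 1:2) {
      v <- coords[z, , k]
      if (!any(flagged)) next
      if (length(tin) < 4) {
        coords[z, flagged, k] <- median(v[tin])
      } else if (smoothing > 0) {
        fit <- stats::smooth.spline(tin, v[tin], spar = smoothing)
        coords[z, flagged, k] <- predict(fit, which(flagged))$y
      } else {
        fit <- splines::interpSpline(tin, v[tin])
        coords[z, flagged, k] <- predict(fit, which(flagged))$y
      }
    }
  }
  new("CenterlineTrack", coords = coords, outlier = outlier,
      source = track@source, repaired = TRUE)
}

#' Realign a series on its centerline
#'
#' Translates every slice-time image by `reference - center` (restricted to
#' the y component by default), using subpixel bilinear resampling with edge
#' clamp — the same interpolation as the registration warper. The reference
#' centerline defaults to the track at the first volume (the default
#' reference-volume policy).
#'
#' @param series a min-max normalized [VolumeSeries-class]
#' @param track a repaired (or outlier-free) [CenterlineTrack-class]
#' @param reference per-slice reference centers: (nz, 2) matrix; default
#'   `trackCoords(track)[, refVolume, ]`
#' @param mode `"y_only"` (default) or `"xy"`
#' @param refVolume volume index used for the default reference (default 1)
#' @return a [RealignmentResult-class]
#' @export
realignSeries <- function(series, track, reference = NULL,
                          mode = c("y_only", "xy"), refVolume = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(series, "VolumeSeries"), is(track, "CenterlineTrack"))
  coords <- track@coords
  if (!track@repaired && (any(track@outlier) || any(is.na(coords))))
    stop("track has unrepaired outliers; run repairOutliers() first")
  d <- series@data
  dm <- dim(d)
  nz <- dm[3]; nt <- dm[4]
  if (is.null(reference)) {
    reference <- coords[, refVolume, , drop = FALSE]
    dim(reference) <- c(nz, 2)
  }
  shifts <- array(0, c(nz, nt, 2))
  for (z in seq_len(nz)) {
    shifts[z, , 1] <- reference[z, 1] - coords[z, , 1]
    shifts[z, , 2] <- reference[z, 2] - coords[z, , 2]
  }
  if (mode == "y_only") shifts[, , 1] <- 0
  if (max(abs(shifts[, , 1])) > dm[1] / 2 ||
      max(abs(shifts[, , 2])) > dm[2] / 2)
    stop("implausible centerline: shift exceeds half the field of view")
  out <- d
  for (z in seq_len(nz)) {
    field <- array(0, c(dm[1], dm[2], 2, nt))
    for (t in seq_len(nt)) {
      field[, , 1, t] <- -shifts[z, t, 1]
      field[, , 2, t] <- -shifts[z, t, 2]
    }
    out[, , z, ] <- warpBatch(array(d[, , z, ], c(dm[1], dm[2], nt)), field)
  }
  new("RealignmentResult",
      series = initialize(series, data = out),
      shifts = shifts, mode = mode)
}

#' Write applied realignment shifts as TSV
#' @param result a [RealignmentResult-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeShiftsTsv <- function(result, path) {
  d <- dim(result@shifts)
  df <- expand.grid(slice = seq_len(d[1]), volume = seq_len(d[2]))
  df$dx <- as.vector(result@shifts[, , 1])
  df$dy <- as.vector(result@shifts[, , 2])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
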