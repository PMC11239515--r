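# Synthetic spinal-cord phantom: bright tubular cord + CSF ring on a dark
# background, corrupted by per-volume in-plane translations (anisotropic,
# dominant y), smooth residual warps and additive Gaussian noise, with the
# full ground-truth motion retained so recovery is measurable.

#' Ground-truth motion applied to a phantom
#'
#' `translations` holds the per-(slice, volume) content translation (dx, dy)
#' in voxels; `warpFields` the per-(slice, volume) smooth residual content
#' displacement. The warper consumed the negated total field (sampling
#' convention `out(p) = template(p + v)`), so the field a registration
#' method aligning volume t back to the template should predict is
#' `+(translation + warp)`: warping the moving image by the content
#' displacement recovers the template.
#'
#' @slot translations (nz, nt, 2) array of content translations in voxels
#' @slot warpFields (nx, ny, 2, nz, nt) array of residual content warps
#' @slot seed the generator seed
#' @export
setClass("GroundTruthMotion",
  representation(translations = "array", warpFields = "array",
                 seed = "numeric"))

#' Phantom configuration
#'
#' Defaults emulate axial cervical-cord gradient-echo EPI: a ~4 mm-radius
#' cord (1.2 mm in-plane voxels), a surrounding CSF ring, 9 slices, 100
#' volumes, and translational motion whose y (anterior-posterior, breathing)
#' variance-to-x ratio is 1.1 : 0.52.
#'
#' @param shape integer length-4 (nx, ny, nz, nt); nx and ny must be
#'   divisible by 16 (network downsampling depth)
#' @param cordRadius,csfRadius radii in voxels; `csfRadius > cordRadius > 0`
#' @param cordIntensity,csfIntensity,backgroundIntensity template intensities
#' @param translationSdY,translationSdX SD of per-volume translations in
#'   voxels (defaults sqrt(1.1) and sqrt(0.52))
#' @param warpAmplitude peak magnitude of the smooth residual warp (voxels)
#' @param warpSmoothness Gaussian scale (voxels) of the residual warp fields
#' @param noiseSd additive Gaussian noise SD (template intensity units)
#' @param seed generator seed
#' @return a list of class `PhantomConfig`
#' @export
phantomConfig <- function(shape = c(64, 64, 9, 100),
                          cordRadius = 3.5, csfRadius = 7,
                          cordIntensity = 1, csfIntensity = 0.6,
                          backgroundIntensity = 0.05,
                          translationSdY = sqrt(1.1),
                          translationSdX = sqrt(0.52),
                          warpAmplitude = 1, warpSmoothness = 8,
                          noiseSd = 0.02, seed = 42) {
  stopifnot(length(shape) == 4, all(shape >= 1))
  if (shape[1] %% 16 != 0 || shape[2] %% 16 != 0)
    stop("nx and ny must be divisible by 16 (network downsampling depth)")
  if (!(csfRadius > cordRadius && cordRadius > 0))
    stop("need csfRadius > cordRadius > 0")
  stopifnot(translationSdY >= 0, translationSdX >= 0,
            warpAmplitude >= 0, noiseSd >= 0)
  structure(as.list(environment()), class = "PhantomConfig")
}

#' Generate a motion-corrupted phantom series with ground truth
#'
#' Volume 1 is the uncorrupted template. Every later volume is the template
#' displaced by a per-volume translation shared across slices plus a smooth
#' residual warp (Gaussian-smoothed white-noise field scaled to
#' `warpAmplitude`), resampled with the same bilinear warper the
#' registration uses, then corrupted with additive Gaussian noise. Masks are
#' drawn on the template; the cord mask is exactly the set of template
#' voxels within `cordRadius` before smoothing. Fully deterministic under
#' `config$seed`.
#'
#' @param config a [phantomConfig()]
#' @return list with `series` ([VolumeSeries-class], raw), `cordMask`,
#'   `csfMask` ([RoiMask-class]) and `truth` ([GroundTruthMotion-class])
#' @export
makePhantom <- function(config = phantomConfig()) {
  stopifnot(inherits(config, "PhantomConfig"))
  nx <- config$shape[1]; ny <- config$shape[2]
  nz <- config$shape[3]; nt <- config$shape[4]
  env <- new.env()
  env$seed <- deriveSeed(config$seed, "phantom")

  # template: cord center drifts gently along z (natural curvature)
  xs <- matrix(0:(nx - 1), nx, ny)
  ys <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)
  template <- array(0, c(nx, ny, nz))
  cord <- array(0, c(nx, ny, nz))
  csf <- array(0, c(nx, ny, nz))
  for (z in seq_len(nz)) {
    cx <- (nx - 1) / 2 + 1.5 * sin(pi * (z - 1) / max(1, nz - 1))
    cy <- (ny - 1) / 2 + 1.0 * cos(pi * (z - 1) / max(1, nz - 1))
    r <- sqrt((xs - cx)^2 + (ys - cy)^2)
    sl <- matrix(config$backgroundIntensity, nx, ny)
    sl[r <= config$csfRadius] <- config$csfIntensity
    sl[r <= config$cordRadius] <- config$cordIntensity
    cord[, , z] <- (sl == config$cordIntensity) + 0
    csf[, , z] <- (sl == config$csfIntensity) + 0
    template[, , z] <- gaussBlurMat(sl, 0.8)
  }

  translations <- array(0, c(nz, nt, 2))
  warpFields <- array(0, c(nx, ny, 2, nz, nt))
  data <- array(0, c(nx, ny, nz, nt))
  data[, , , 1] <- template

  withRngStream(env, {
    for (t in seq_len(nt)[-1]) {
      dx <- rnorm(1, 0, config$translationSdX)
      dy <- rnorm(1, 0, config$translationSdY)
      for (z in seq_len(nz)) {
        translations[z, t, ] <- c(dx, dy)
        w <- array(0, c(nx, ny, 2))
        if (config$warpAmplitude > 0) {
          w[, , 1] <- gaussBlurMat(matrix(rnorm(nx * ny), nx, ny),
                                   config$warpSmoothness)
          w[, , 2] <- gaussBlurMat(matrix(rnorm(nx * ny), nx, ny),
                                   config$warpSmoothness)
          mag <- max(sqrt(w[, , 1]^2 + w[, , 2]^2))
          if (mag > 0) w <- w * (config$warpAmplitude / mag)
        }
        warpFields[, , , z, t] <- w
        sampling <- array(0, c(nx, ny, 2))
        sampling[, , 1] <- -(dx + w[, , 1])
        sampling[, , 2] <- -(dy + w[, , 2])
        moved <- warpSlice(template[, , z], sampling)
        if (config$noiseSd > 0)
          moved <- moved + matrix(rnorm(nx * ny, 0, config$noiseSd), nx, ny)
        data[, , z, t] <- moved
      }
    }
    TRUE
  })

  list(series = volumeSeries(data),
       cordMask = roiMask(cord, "cord"),
       csfMask = roiMask(csf, "csf"),
       truth = new("GroundTruthMotion", translations = translations,
                   warpFields = warpFields, seed = config$seed))
}

#' Undo phantom motion using the stored ground truth
#'
#' Resamples every corrupted volume with the stored content displacement
#' (exact for pure translations, first-order for the smooth residual warp),
#' giving the best-case corrected series any method could aim for.
#'
#' @param series the phantom [VolumeSeries-class]
#' @param truth the matching [GroundTruthMotion-class]
#' @return the dewarped [VolumeSeries-class]
#' @export
groundTruthCorrect <- function(series, truth) {
  d <- series@data
  dm <- dim(d)
  for (t in seq_len(dm[4])[-1]) {
    for (z in seq_len(dm[3])) {
      u <- truth@warpFields[, , , z, t]
      u[, , 1] <- u[, , 1] + truth@translations[z, t, 1]
      u[, , 2] <- u[, , 2] + truth@translations[z, t, 2]
      d[, , z, t] <- warpSlice(series@data[, , z, t], u)
    }
  }
  initialize(series, data = d)
}

#' Mean endpoint error of predicted displacement fields
#'
#' Euclidean distance between the predicted fields and the ground-truth
#' content displacement, averaged over cord-mask pixels, slices and all
#' corrupted volumes. `extraShifts` folds in a translation already applied
#' upstream (centerline realignment): the prediction credited to a volume
#' is then `field - appliedShift`, the network's residual plus what the
#' realignment already removed, compared against the original motion.
#'
#' @param fields (nx, ny, 2, nz, nt) predicted sampling fields
#' @param truth a [GroundTruthMotion-class]
#' @param cordMask a [RoiMask-class]
#' @param extraShifts optional (nz, nt, 2) applied content shifts
#' @return scalar mean endpoint error in voxels
#' @export
meanEndpointError <- function(fields, truth, cordMask, extraShifts = NULL) {
  dm <- dim(fields)
  nz <- dm[4]; nt <- dm[5]
  err <- 0; npx <- 0
  for (t in seq_len(nt)[-1]) {
    for (z in seq_len(nz)) {
      m <- cordMask@data[, , z] > 0
      if (!any(m)) next
      gt1 <- truth@translations[z, t, 1] + truth@warpFields[, , 1, z, t]
      gt2 <- truth@translations[z, t, 2] + truth@warpFields[, , 2, z, t]
      p1 <- fields[, , 1, z, t]; p2 <- fields[, , 2, z, t]
      if (!is.null(extraShifts)) {
        p1 <- p1 - extraShifts[z, t, 1]
        p2 <- p2 - extraShifts[z, t, 2]
      }
      e <- sqrt((p1 - gt1)^2 + (p2 - gt2)^2)
      err <- err + sum(e[m]); npx <- npx + sum(m)
    }
  }
  err / npx
}
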