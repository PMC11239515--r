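# Fixtures are generated in code: small phantoms, smooth test images and
# hand-built series. All randomness is seeded per call site.

# A smooth Gaussian bump image (H x W), center in 0-based voxel coordinates.
gaussImage <- function(H, W, cx, cy, sigma = 3) {
  xs <- matrix(0:(H - 1), H, W)
  ys <- matrix(0:(W - 1), H, W, byrow = TRUE)
  exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
}

# Small normalized phantom run bundled for training tests.
phantomRun <- function(seed, shape = c(32, 32, 2, 24), warpAmplitude = 0,
                       noiseSd = 0.01, ...) {
  ph <- makePhantom(phantomConfig(shape = shape, cordRadius = 3,
                                  csfRadius = 6,
                                  warpAmplitude = warpAmplitude,
                                  noiseSd = noiseSd, seed = seed, ...))
  list(run = fmriRun(minmaxNormalize(ph$series),
                     subject = paste0("s", seed),
                     cordMask = ph$cordMask, csfMask = ph$csfMask,
                     truth = ph$truth),
       phantom = ph)
}

# A displacement field whose sampling positions stay away from bilinear
# kinks (fractional parts well inside (0, 1)), for finite-difference checks.
kinkFreeField <- function(H, W, seed = 1) {
  set.seed(seed)
  array(runif(H * W * 2, 0.2, 0.4) * sample(c(-1, 1), H * W * 2, TRUE),
        c(H, W, 2))
}

# Brute-force windowed-NCC oracle: explicit loops over clamped windows.
nccOracle <- function(f, w, n = 3, eps = 1e-5) {
  H <- nrow(f); W <- ncol(f); k <- n %/% 2
  r2 <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    ii <- pmin(pmax((i - k):(i + k), 1), H)
    jj <- pmin(pmax((j - k):(j + k), 1), W)
    fv <- as.vector(f[ii, jj]); wv <- as.vector(w[ii, jj])
    a <- sum((fv - mean(fv)) * (wv - mean(wv)))
    b <- sum((fv - mean(fv))^2); cc <- sum((wv - mean(wv))^2)
    r2[i, j] <- a^2 / (b * cc + eps)
  }
  -mean(r2)
}

# Hand-built track: one slice, given y values, constant x.
trackFromY <- function(y, x = 10) {
  nt <- length(y)
  coords <- array(NA_real_, c(1, nt, 2))
  coords[1, , 1] <- x
  coords[1, , 2] <- y
  new("CenterlineTrack", coords = coords,
      outlier = matrix(FALSE, 1, nt), source = "external",
      repaired = FALSE)
}

simLossOf <- function(sim, f, w) {
  if (sim == "mse") mseLoss(f, w, lossConfig("mse"))
  else nccLoss(f, w, lossConfig("ncc"))
}
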