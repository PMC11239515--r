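seriesOfVoxels <- function(...) {
  # build a series from per-volume scalar fills on a 2x2x1 grid
  vols <- list(...)
  arr <- array(0, c(2, 2, 1, length(vols)))
  for (t in seq_along(vols)) arr[, , 1, t] <- vols[[t]]
  volumeSeries(arr)
}

test_that("tSNR follows the sample-SD oracle and its conventions", {
  s <- seriesOfVoxels(1, 3)
  r <- tsnr(s)
  expect_equal(r$map[1, 1, 1], sqrt(2), tolerance = 1e-12)  # 2 / sd([1,3])
  expect_equal(r$mean, sqrt(2), tolerance = 1e-12)
  # constant time course maps to 0 by convention
  expect_identical(tsnr(seriesOfVoxels(7, 7, 7))$map[1, 1, 1], 0)
  # scale invariance
  set.seed(70)
  arr <- array(runif(4 * 4 * 2 * 6) + 1, c(4, 4, 2, 6))
  a <- tsnr(volumeSeries(arr))$map
  b <- tsnr(volumeSeries(3.7 * arr))$map
  expect_equal(a, b, tolerance = 1e-9)
  expect_error(tsnr(seriesOfVoxels(1)), "2 volumes")
})

test_that("DVARS is the RMS frame difference on normalized data", {
  arr <- array(0, c(2, 2, 1, 2)); arr[, , 1, 2] <- 1
  s <- volumeSeries(arr); s@normalized <- "minmax"
  # rescale by hand so the frame step is exactly 2 on a 0..2 scale:
  # equivalently check on 0/1 data that DVARS = 1, then linearity
  r <- dvars(s)
  expect_identical(r$series, 1)
  # all-0 -> all-2 frames on an already-normalized pair
  arr2 <- array(0, c(3, 3, 1, 3))
  arr2[, , 1, 2] <- 1; arr2[, , 1, 3] <- 1
  s2 <- volumeSeries(arr2); s2@normalized <- "minmax"
  r2 <- dvars(s2)
  expect_equal(r2$series, c(1, 0))
  expect_equal(r2$mean, 0.5)
  # spatial permutation invariance
  set.seed(71)
  arr3 <- array(runif(16 * 2), c(4, 4, 1, 2))
  p <- sample(16)
  arr4 <- arr3
  arr4[, , 1, 1] <- matrix(as.vector(arr3[, , 1, 1])[p], 4, 4)
  arr4[, , 1, 2] <- matrix(as.vector(arr3[, , 1, 2])[p], 4, 4)
  s3 <- volumeSeries(arr3); s3@normalized <- "minmax"
  s4 <- volumeSeries(arr4); s4@normalized <- "minmax"
  expect_equal(dvars(s3)$series, dvars(s4)$series, tolerance = 1e-12)
  expect_error(dvars(volumeSeries(arr3)), "normalize")
})

test_that("volume correlation scores copies at 1 and handles degeneracy", {
  set.seed(72)
  ref <- array(runif(4 * 4 * 2), c(4, 4, 2))
  arr <- array(rep(ref, 3), c(4, 4, 2, 3))
  s <- volumeSeries(arr)
  r <- volumeCC(s, ref)
  expect_equal(r$series, rep(1, 3), tolerance = 1e-12)
  # negated mean-centered reference correlates at -1
  neg <- array(rep(2 * mean(ref) - ref, 1), c(4, 4, 2, 1))
  expect_equal(volumeCC(volumeSeries(neg), ref)$series, -1,
               tolerance = 1e-12)
  # constant volume: flagged, scored 0
  cst <- array(5, c(4, 4, 2, 1))
  expect_warning(rc <- volumeCC(volumeSeries(cst), ref), "constant")
  expect_identical(rc$series, 0)
  expect_true(rc$degenerate[1])
})

test_that("independent random volumes decorrelate from the reference", {
  means <- vapply(1:3, function(sd0) {
    set.seed(200 + sd0)
    ref <- array(runif(64 * 64 * 4), c(64, 64, 4))
    arr <- array(runif(64 * 64 * 4 * 8), c(64, 64, 4, 8))
    volumeCC(volumeSeries(arr), ref)$mean
  }, numeric(1))
  expect_true(all(abs(means) < 0.05))
})

test_that("qc comparison of identical series yields identical rows", {
  set.seed(73)
  arr <- array(runif(8 * 8 * 2 * 5), c(8, 8, 2, 5))
  s <- minmaxNormalize(volumeSeries(arr))
  q <- qcReport(s, s)
  raw <- subset(q$table, method == "raw")
  cor <- subset(q$table, method == "corrected")
  expect_equal(raw$value, cor$value, tolerance = 1e-12)
  # round trip through CSV
  f <- tempfile(fileext = ".csv")
  writeQcCsv(q$table, f)
  back <- readQcCsv(f)
  expect_equal(back$value, q$table$value, tolerance = 1e-9)
  expect_identical(back$metric, q$table$metric)
})

test_that("ground-truth dewarping beats the corrupted series on QC", {
  ph <- makePhantom(phantomConfig(shape = c(32, 32, 2, 12), cordRadius = 3,
                                  csfRadius = 6, warpAmplitude = 0.5,
                                  noiseSd = 0.01, seed = 74))
  raw <- minmaxNormalize(ph$series)
  twin <- minmaxNormalize(groundTruthCorrect(ph$series, ph$truth))
  expect_gt(tsnr(twin, ph$cordMask)$mean, tsnr(raw, ph$cordMask)$mean)
  expect_lt(dvars(twin)$mean, dvars(raw)$mean)
})

test_that("noise moves tSNR down and DVARS up, monotonically", {
  vals <- lapply(c(0.01, 0.05, 0.1), function(ns) {
    ph <- makePhantom(phantomConfig(shape = c(32, 32, 1, 10), cordRadius = 3,
                                    csfRadius = 6, warpAmplitude = 0,
                                    translationSdX = 0, translationSdY = 0,
                                    noiseSd = ns, seed = 75))
    s <- minmaxNormalize(ph$series)
    c(tsnr = tsnr(s, ph$cordMask)$mean, dvars = dvars(s)$mean)
  })
  ts <- vapply(vals, `[[`, numeric(1), "tsnr")
  dv <- vapply(vals, `[[`, numeric(1), "dvars")
  expect_true(all(diff(ts) < 0))
  expect_true(all(diff(dv) > 0))
})

test_that("ground-truth realignment maximizes cord tSNR over partial fixes", {
  ph <- makePhantom(phantomConfig(shape = c(32, 32, 1, 12), cordRadius = 3,
                                  csfRadius = 6, warpAmplitude = 0,
                                  noiseSd = 0.005, seed = 76))
  applyShift <- function(frac) {
    d <- seriesData(ph$series)
    for (t in 2:12) {
      u <- array(0, c(32, 32, 2))
      u[, , 1] <- frac * ph$truth@translations[1, t, 1]
      u[, , 2] <- frac * ph$truth@translations[1, t, 2]
      d[, , 1, t] <- warpSlice(seriesData(ph$series)[, , 1, t], u)
    }
    minmaxNormalize(volumeSeries(d))
  }
  t0 <- tsnr(applyShift(0), ph$cordMask)$mean
  t5 <- tsnr(applyShift(0.5), ph$cordMask)$mean
  t1 <- tsnr(applyShift(1), ph$cordMask)$mean
  expect_gt(t1, t5)
  expect_gt(t5, t0)
})

test_that("tSNR maps export as NIfTI", {
  set.seed(77)
  arr <- array(runif(4 * 4 * 2 * 5) + 1, c(4, 4, 2, 5))
  m <- tsnr(volumeSeries(arr))$map
  p <- tempfile(fileext = ".nii.gz")
  writeTsnrNifti(m, p)
  img <- RNifti::readNifti(p)
  expect_equal(structure(as.vector(img), dim = dim(img)), m,
               tolerance = 1e-12)
})
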