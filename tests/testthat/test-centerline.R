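# Helpers build tiny single-blob series whose true center is known.

blobSeries <- function(centers, H = 32, W = 32) {
  # centers: nt x 2 matrix of (x, y) blob centers, one slice
  nt <- nrow(centers)
  arr <- array(0, c(H, W, 1, nt))
  for (t in seq_len(nt))
    arr[, , 1, t] <- gaussImage(H, W, centers[t, 1], centers[t, 2], sigma = 3)
  minmaxNormalize(volumeSeries(arr))
}

test_that("centroid extraction recovers a symmetric blob center", {
  s <- blobSeries(matrix(c(14, 10), 1, 2))
  tr <- extractCenterline(s)
  expect_lt(abs(trackCoords(tr)[1, 1, 1] - 14), 0.1)
  expect_lt(abs(trackCoords(tr)[1, 1, 2] - 10), 0.1)
  expect_false(any(trackOutliers(tr)))
})

test_that("a single-voxel mask pins the centroid exactly", {
  arr <- array(0.5, c(16, 16, 1, 5))
  m <- array(0, c(16, 16, 1)); m[6, 8, 1] <- 1    # 0-based (5, 7)
  s <- minmaxNormalize(volumeSeries(arr + 0.5 * (slice.index(arr, 1) == 6)))
  tr <- extractCenterline(s, roiMask(m, "cord"))
  expect_identical(trackCoords(tr)[1, 1, ], c(5, 7))
})

test_that("all-zero slices are flagged as outliers, not errors", {
  arr <- array(0, c(16, 16, 1, 6))
  arr[, , 1, 2:6] <- gaussImage(16, 16, 8, 8)     # t = 1 stays empty
  s <- volumeSeries(arr); s@normalized <- "minmax"
  tr <- extractCenterline(s)
  expect_true(trackOutliers(tr)[1, 1])
  expect_true(all(!trackOutliers(tr)[1, 2:6]))
})

test_that("IQR fences flag a planted spike and the spline repairs it", {
  tr <- trackFromY(c(5, 5, 5, 5, 25))
  rep <- repairOutliers(tr)
  expect_true(trackOutliers(rep)[1, 5])
  expect_equal(trackCoords(rep)[1, 5, 2], 5, tolerance = 1e-9)
  expect_true(rep@repaired)
})

test_that("outlier-free tracks pass through unchanged", {
  y <- 10 + sin(seq(0, 2 * pi, length.out = 12))
  tr <- trackFromY(y)
  rep <- repairOutliers(tr)
  expect_equal(trackCoords(rep)[1, , 2], y, tolerance = 1e-6)
  expect_false(any(trackOutliers(rep)))
})

test_that("spline repair recovers a clean sinusoid under a planted spike", {
  t <- 1:30
  clean <- 12 + 2 * sin(2 * pi * t / 15)
  y <- clean; y[17] <- y[17] + 12
  rep <- repairOutliers(trackFromY(y))
  expect_true(trackOutliers(rep)[1, 17])
  expect_lt(abs(trackCoords(rep)[1, 17, 2] - clean[17]), 0.2)
})

test_that("an all-outlier slice raises a named error", {
  coords <- array(NA_real_, c(2, 6, 2))
  coords[1, , ] <- 5
  tr <- new("CenterlineTrack", coords = coords,
            outlier = matrix(c(rep(FALSE, 6), rep(TRUE, 6)), 2, 6,
                             byrow = TRUE),
            source = "external", repaired = FALSE)
  expect_error(repairOutliers(tr), "slice 2")
})

test_that("realignment recovers a planted +3 voxel y shift", {
  # moderate spread keeps the +3 excursion inside the IQR fences
  ys <- c(14, 17, 15, 12, 16)                  # +3 content shift at t=2
  s <- blobSeries(cbind(15.5, ys))
  tr <- repairOutliers(extractCenterline(s), smoothing = 0)
  expect_false(any(trackOutliers(tr)))
  ra <- realignSeries(s, tr)
  expect_lt(abs(ra@shifts[1, 2, 2] - (-3)), 0.5)
  expect_identical(ra@shifts[1, 2, 1], 0)      # y_only zeroes x
  tr2 <- extractCenterline(ra@series)
  dev <- abs(trackCoords(tr2)[1, 2, 2] - trackCoords(tr2)[1, 1, 2])
  expect_lt(dev, 0.5)
})

test_that("y-only mode ignores pure x displacement", {
  centers <- cbind(c(12, 15, 13, 14, 12.5), 16)  # pure x motion
  s <- blobSeries(centers)
  tr <- repairOutliers(extractCenterline(s))
  ra <- realignSeries(s, tr, mode = "y_only")
  expect_true(all(ra@shifts == 0) ||
                max(abs(ra@shifts[, , 2])) < 0.05)
  expect_equal(seriesData(ra@series), seriesData(s), tolerance = 1e-6)
})

test_that("zero-deviation tracks give a bitwise identity transform", {
  s <- blobSeries(matrix(rep(c(16, 16), 5), 5, 2, byrow = TRUE))
  tr <- extractCenterline(s)
  ra <- realignSeries(s, repairOutliers(tr))
  expect_identical(seriesData(ra@series), seriesData(s))
})

test_that("realignment reduces centerline temporal variance and is idempotent", {
  set.seed(40)
  yc <- 16 + rnorm(10, 0, 1.5)
  s <- blobSeries(cbind(16, yc))
  tr <- repairOutliers(extractCenterline(s))
  v0 <- var(trackCoords(tr)[1, , 2])
  ra <- realignSeries(s, tr)
  tr1 <- extractCenterline(ra@series)
  v1 <- var(trackCoords(tr1)[1, , 2])
  expect_lt(v1, v0)
  # second pass changes shifts by < 0.5 voxel
  ra2 <- realignSeries(ra@series, repairOutliers(tr1))
  expect_lt(max(abs(ra2@shifts)), 0.5)
})

test_that("xy mode never leaves a larger residual than y-only", {
  set.seed(41)
  centers <- cbind(16 + rnorm(8, 0, 0.8), 16 + rnorm(8, 0, 1.2))
  s <- blobSeries(centers)
  tr <- repairOutliers(extractCenterline(s))
  resid <- function(mode) {
    ra <- realignSeries(s, tr, mode = mode)
    t2 <- trackCoords(extractCenterline(ra@series))
    mean(sqrt((t2[1, , 1] - t2[1, 1, 1])^2 + (t2[1, , 2] - t2[1, 1, 2])^2))
  }
  expect_lte(resid("xy"), resid("y_only") + 1e-6)
})

test_that("implausible shifts and unrepaired tracks are refused", {
  s <- blobSeries(matrix(rep(c(16, 16), 5), 5, 2, byrow = TRUE))
  coords <- array(NA_real_, c(1, 5, 2))
  tr <- new("CenterlineTrack", coords = coords,
            outlier = matrix(TRUE, 1, 5), source = "external",
            repaired = FALSE)
  expect_error(realignSeries(s, tr), "unrepaired")
  # a reference 20 voxels off-center exceeds half the field of view
  good <- extractCenterline(s)
  farRef <- matrix(c(16, 36), 1, 2)
  expect_error(realignSeries(s, good, reference = farRef, mode = "xy"),
               "half the field of view")
})
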