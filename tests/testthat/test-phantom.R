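test_that("motion-free phantom repeats its template exactly", {
  ph <- makePhantom(phantomConfig(shape = c(32, 32, 2, 5), cordRadius = 3,
                                  csfRadius = 6, translationSdX = 0,
                                  translationSdY = 0, warpAmplitude = 0,
                                  noiseSd = 0, seed = 1))
  d <- seriesData(ph$series)
  for (t in 2:5) expect_identical(d[, , , t], d[, , , 1])
})

test_that("corrupted volumes are the template moved by the stored truth", {
  ph <- makePhantom(phantomConfig(shape = c(32, 32, 1, 6), cordRadius = 3,
                                  csfRadius = 6, translationSdY = 1.5,
                                  warpAmplitude = 0, noiseSd = 0, seed = 3))
  d <- seriesData(ph$series)
  tmpl <- d[, , 1, 1]
  for (t in 2:6) {
    v <- array(0, c(32, 32, 2))
    v[, , 1] <- -ph$truth@translations[1, t, 1]
    v[, , 2] <- -ph$truth@translations[1, t, 2]
    expect_equal(d[, , 1, t], warpSlice(tmpl, v), tolerance = 1e-12)
  }
  # direct array-shift oracle for an exact (0, +2) content translation
  v2 <- array(0, c(32, 32, 2)); v2[, , 2] <- -2
  moved <- warpSlice(tmpl, v2)
  expect_equal(moved[, 3:32], tmpl[, 1:30], tolerance = 1e-12)
})

test_that("generator is bitwise deterministic under its seed", {
  cfg <- phantomConfig(shape = c(32, 32, 2, 6), cordRadius = 3,
                       csfRadius = 6, seed = 7)
  a <- makePhantom(cfg); b <- makePhantom(cfg)
  expect_identical(seriesData(a$series), seriesData(b$series))
  expect_identical(a$truth@translations, b$truth@translations)
  expect_identical(a$truth@warpFields, b$truth@warpFields)
})

test_that("cord mask is exactly the template cord region before smoothing", {
  cfg <- phantomConfig(shape = c(32, 32, 3, 2), cordRadius = 3, csfRadius = 6,
                       seed = 2)
  ph <- makePhantom(cfg)
  for (z in 1:3) {
    cx <- (32 - 1) / 2 + 1.5 * sin(pi * (z - 1) / 2)
    cy <- (32 - 1) / 2 + 1.0 * cos(pi * (z - 1) / 2)
    xs <- matrix(0:31, 32, 32); ys <- matrix(0:31, 32, 32, byrow = TRUE)
    inside <- (sqrt((xs - cx)^2 + (ys - cy)^2) <= 3) + 0
    expect_identical(maskData(ph$cordMask)[, , z], inside)
  }
  expect_true(all(maskData(ph$cordMask) * maskData(ph$csfMask) == 0))
})

test_that("default anisotropy yields larger y- than x-translation variance", {
  ph <- makePhantom(phantomConfig(shape = c(32, 32, 1, 120), cordRadius = 3,
                                  csfRadius = 6, warpAmplitude = 0,
                                  noiseSd = 0, seed = 5))
  tr <- ph$truth@translations
  expect_gt(var(tr[1, -1, 2]), var(tr[1, -1, 1]))
})

test_that("ground-truth correction restores the template up to resampling", {
  ph <- makePhantom(phantomConfig(shape = c(32, 32, 1, 8), cordRadius = 3,
                                  csfRadius = 6, warpAmplitude = 0,
                                  noiseSd = 0, seed = 6))
  fixed <- groundTruthCorrect(ph$series, ph$truth)
  d0 <- seriesData(ph$series)
  d1 <- seriesData(fixed)
  tmpl <- d0[5:28, 5:28, 1, 1]
  before <- vapply(2:8, function(t) mean(abs(d0[5:28, 5:28, 1, t] - tmpl)),
                   numeric(1))
  after <- vapply(2:8, function(t) mean(abs(d1[5:28, 5:28, 1, t] - tmpl)),
                  numeric(1))
  # two bilinear resamples are lossy; demand a large aggregate reduction
  expect_lt(mean(after), 0.25 * mean(before))
  expect_true(all(after <= before + 1e-12))
})

test_that("invalid phantom configurations are refused", {
  expect_error(phantomConfig(shape = c(30, 32, 2, 5)), "divisible by 16")
  expect_error(phantomConfig(cordRadius = 7, csfRadius = 6), "csfRadius")
})
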