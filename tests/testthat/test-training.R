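test_that("reference policies follow their conventions", {
  set.seed(60)
  arr <- array(rnorm(4 * 4 * 2 * 5), c(4, 4, 2, 5))
  s <- volumeSeries(arr)
  expect_identical(selectReference(s, "first"), array(arr[, , , 1], c(4, 4, 2)))
  # nt = 5: mid is 0-based floor(5/2) = 2, i.e. the third volume
  expect_identical(selectReference(s, "mid"), array(arr[, , , 3], c(4, 4, 2)))
  a <- array(1, c(4, 4, 2, 2)); a[, , , 2] <- 3
  expect_equal(selectReference(volumeSeries(a), "mean"),
               array(2, c(4, 4, 2)))
  expect_error(selectReference(s, "last"))
})

makeTinyRuns <- function(subjects, nt = 6) {
  lapply(subjects, function(s) {
    set.seed(1000 + s)
    arr <- array(runif(16 * 16 * 2 * nt), c(16, 16, 2, nt))
    fmriRun(minmaxNormalize(volumeSeries(arr)), subject = paste0("s", s))
  })
}

test_that("pair generator splits subjects disjointly and deterministically", {
  runs <- makeTinyRuns(1:4)
  cfg <- trainConfig(batchSize = 6, splitFraction = 0.5, seed = 3)
  gen <- makePairGenerator(runs, cfg)
  expect_length(gen$trainSubjects, 2)
  expect_length(gen$valSubjects, 2)
  expect_length(intersect(gen$trainSubjects, gen$valSubjects), 0)
  b1 <- gen$nextBatch(6, "train")
  expect_true(all(b1$provenance$subject %in% gen$trainSubjects))
  bv <- gen$nextBatch(6, "val")
  expect_true(all(bv$provenance$subject %in% gen$valSubjects))
  # identical stream on reconstruction
  gen2 <- makePairGenerator(runs, cfg)
  b2 <- gen2$nextBatch(6, "train")
  expect_identical(b1$fixed, b2$fixed)
  expect_identical(b1$provenance, b2$provenance)
  expect_error(makePairGenerator(list(), cfg), "empty")
})

test_that("subject sampling is uniform within binomial bounds", {
  runs <- makeTinyRuns(1:3)
  cfg <- trainConfig(batchSize = 100, splitFraction = 0.67, seed = 5)
  gen <- makePairGenerator(runs, cfg)
  expect_length(gen$trainSubjects, 2)
  counts <- table(do.call(rbind, lapply(1:100, function(i)
    gen$nextBatch(100, "train")$provenance))$subject)
  n <- 10000; p <- 0.5
  bound <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) < bound))
})

test_that("short training halves the loss on translation-only phantoms", {
  runs <- lapply(1:3, function(s) phantomRun(s)$run)
  cfg <- trainConfig(learningRate = 1e-3, batchSize = 8, epochs = 4,
                     stepsPerEpoch = 50,
                     loss = lossConfig("mse", lambda = 0.01), seed = 7)
  tr <- trainModel(runs, modelSpec("drm2"), cfg)
  h <- tr$history
  expect_identical(nrow(h), 4L)
  expect_true(all(is.finite(h$valLoss)))
  # trained loss under half the untrained loss, on one held-out batch
  gen <- makePairGenerator(runs, cfg)
  batch <- gen$nextBatch(16, "val")
  untrained <- SpineMoCo:::evalLoss(buildModel(modelSpec("drm2"),
                                               seed = cfg$seed), batch, cfg)
  trained <- SpineMoCo:::evalLoss(tr$weights, batch, cfg)
  expect_lt(trained, 0.5 * untrained)
})

test_that("a zero-motion phantom trains to a near-identity map", {
  runs <- lapply(1:2, function(s)
    phantomRun(s, translationSdX = 0, translationSdY = 0, noiseSd = 0.005)$run)
  cfg <- trainConfig(learningRate = 1e-3, batchSize = 8, epochs = 1,
                     stepsPerEpoch = 40,
                     loss = lossConfig("mse", lambda = 0.01), seed = 8)
  tr <- suppressWarnings(trainModel(runs, modelSpec("drm2"), cfg))
  v <- runs[[2]]
  cor <- correctSeries(v$series, tr$weights)
  expect_lt(mean(abs(cor$fields)), 0.1)
  expect_lt(mean(abs(seriesData(cor$series) - seriesData(v$series))), 0.01)
})

test_that("correction emits one field per slice and volume, padding as needed", {
  set.seed(61)
  w <- buildModel(modelSpec("drm2"), seed = 1)
  arr <- array(runif(40 * 40 * 3 * 4), c(40, 40, 3, 4))
  s <- minmaxNormalize(volumeSeries(arr))
  cor <- correctSeries(s, w)   # 40 not divisible by 16: pad to 48, crop back
  expect_identical(dim(cor$fields), c(40L, 40L, 2L, 3L, 4L))
  expect_identical(dim(seriesData(cor$series)), dim(arr))
  expect_true(all(is.finite(cor$fields)))
  expect_error(correctSeries(volumeSeries(arr), w), "normalized")
})

test_that("training aborts with a diagnostic on divergence", {
  runs <- makeTinyRuns(1:2)
  # an absurd intensity scale drives the first similarity loss to Inf
  cfg <- trainConfig(learningRate = 1e-3, batchSize = 4, epochs = 1,
                     stepsPerEpoch = 5,
                     loss = lossConfig("mse", imageSigma = 1e-200), seed = 2)
  expect_error(suppressWarnings(trainModel(runs, modelSpec("drm2"), cfg)),
               "diverged|non-finite")
})
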