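# Reference selection, subject-disjoint pair sampling, the unsupervised
# optimization loop, and whole-run inference.

#' Training configuration
#'
#' Defaults are the full-scale settings (Adam at 1e-4, batches of 100 slice
#' pairs, 200 epochs of 150 iterations, subject-level 70:30 split,
#' first-volume reference). Reduced-scale runs override epochs, steps,
#' batch size and learning rate through these same fields.
#'
#' @param learningRate Adam learning rate (default 1e-4)
#' @param batchSize slice pairs per batch (default 100)
#' @param epochs training epochs (default 200)
#' @param stepsPerEpoch optimizer steps per epoch (default 150)
#' @param splitFraction train fraction of subjects (default 0.7)
#' @param referencePolicy `"first"`, `"mid"` or `"mean"`
#' @param loss a [lossConfig()]
#' @param seed seed governing split, sampling and initialization
#' @return a list of class `TrainConfig`
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 100, epochs = 200,
                        stepsPerEpoch = 150, splitFraction = 0.7,
                        referencePolicy = c("first", "mid", "mean"),
                        loss = lossConfig(), seed = 1) {
  referencePolicy <- match.arg(referencePolicy)
  stopifnot(splitFraction > 0, splitFraction < 1, batchSize >= 1,
            epochs >= 1, stepsPerEpoch >= 1, learningRate > 0)
  structure(list(learningRate = learningRate, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 stepsPerEpoch = as.integer(stepsPerEpoch),
                 splitFraction = splitFraction,
                 referencePolicy = referencePolicy, loss = loss,
                 seed = seed), class = "TrainConfig")
}

#' Bundle a run for training
#'
#' @param series a min-max normalized [VolumeSeries-class]
#' @param subject subject identifier (split unit)
#' @param run run identifier
#' @param cordMask,csfMask optional [RoiMask-class] (cord mask enables the
#'   tSNR-based validation criterion)
#' @param truth optional [GroundTruthMotion-class] for phantoms
#' @return a list of class `fmriRun`
#' @export
fmriRun <- function(series, subject, run = "run1", cordMask = NULL,
                    csfMask = NULL, truth = NULL) {
  stopifnot(is(series, "VolumeSeries"))
  structure(list(series = series, subject = as.character(subject),
                 run = as.character(run), cordMask = cordMask,
                 csfMask = csfMask, truth = truth), class = "fmriRun")
}

#' Select the reference volume of a series
#'
#' @param series a [VolumeSeries-class]
#' @param policy `"first"` (volume 1), `"mid"` (0-based floor(nt/2)) or
#'   `"mean"` (voxelwise average over time)
#' @return a 3D array (nx, ny, nz)
#' @export
selectReference <- function(series, policy = c("first", "mid", "mean")) {
  policy <- match.arg(policy)
  d <- series@data
  dm <- dim(d)
  switch(policy,
    first = array(d[, , , 1], dm[1:3]),
    mid = array(d[, , , floor(dm[4] / 2) + 1L], dm[1:3]),
    mean = array(rowMeans(matrix(d, ncol = dm[4])), dm[1:3]))
}

#' Subject-disjoint slice-pair generator
#'
#' Splits subjects into train and validation sets (subject-disjoint), then
#' samples batches by drawing subject, run, slice and volume uniformly;
#' fixed = the run's reference slice, moving = the sampled slice-time image.
#' Seed-deterministic: two generators built with the same runs and config
#' produce identical batch streams.
#'
#' @param runs list of [fmriRun()] objects
#' @param config a [trainConfig()]
#' @return a generator environment with `$nextBatch(split)`,
#'   `$trainSubjects`, `$valSubjects`
#' @export
makePairGenerator <- function(runs, config = trainConfig()) {
  if (length(runs) == 0) stop("empty run list")
  stopifnot(all(vapply(runs, inherits, logical(1), "fmriRun")))
  subjects <- unique(vapply(runs, `[[`, character(1), "subject"))
  gen <- new.env()
  gen$seed <- deriveSeed(config$seed, "pairs")
  gen$rngState <- NULL
  ord <- withRngStream(gen, sample(subjects))
  nTrain <- max(1L, round(config$splitFraction * length(subjects)))
  if (length(subjects) >= 2L) nTrain <- min(nTrain, length(subjects) - 1L)
  gen$trainSubjects <- sort(ord[seq_len(nTrain)])
  gen$valSubjects <- if (length(subjects) >= 2L)
    sort(ord[-seq_len(nTrain)]) else gen$trainSubjects
  if (length(subjects) < 2L)
    warning("single subject: validation set equals training set")
  refs <- lapply(runs, function(r)
    selectReference(r$series, config$referencePolicy))
  runSubj <- vapply(runs, `[[`, character(1), "subject")
  gen$nextBatch <- function(n = config$batchSize, split = "train") {
    subj <- if (split == "train") gen$trainSubjects else gen$valSubjects
    withRngStream(gen, {
      d1 <- dim(runs[[1]]$series@data)
      fixed <- array(0, c(d1[1], d1[2], n))
      moving <- array(0, c(d1[1], d1[2], n))
      prov <- data.frame(subject = character(n), run = character(n),
                         z = integer(n), t = integer(n),
                         stringsAsFactors = FALSE)
      for (i in seq_len(n)) {
        s <- subj[sample.int(length(subj), 1L)]
        cand <- which(runSubj == s)
        ri <- cand[sample.int(length(cand), 1L)]
        dm <- dim(runs[[ri]]$series@data)
        z <- sample.int(dm[3], 1L)
        t <- sample.int(dm[4], 1L)
        fixed[, , i] <- refs[[ri]][, , z]
        moving[, , i] <- runs[[ri]]$series@data[, , z, t]
        prov$subject[i] <- s; prov$run[i] <- runs[[ri]]$run
        prov$z[i] <- z; prov$t[i] <- t
      }
      list(fixed = fixed, moving = moving, provenance = prov)
    })
  }
  gen
}

# One optimization step on a batch; returns loss, grads and updated weights
# (BN running stats).
trainStep <- function(weights, batch, config) {
  d <- dim(batch$fixed)
  x <- array(0, c(d[1], d[2], 2L, d[3]))
  x[, , 1, ] <- batch$fixed
  x[, , 2, ] <- batch$moving
  fw <- netForward(weights, x, train = TRUE)
  flow <- fw$flow
  warped <- warpBatch(batch$moving, flow)
  sim <- simLossGradBatch(batch$fixed, warped, config$loss)
  wb <- warpBatchGrad(batch$moving, flow, sim$grad)
  gflow <- wb$gfield
  loss <- sim$loss
  if (config$loss$lambda > 0) {
    sm <- smoothnessBatch(flow)
    loss <- loss + config$loss$lambda * sm$loss
    gflow <- gflow + config$loss$lambda * sm$grad
  }
  grads <- netBackward(fw$weights, fw$caches, gflow)
  list(loss = loss, grads = grads, weights = fw$weights)
}

evalLoss <- function(weights, batch, config) {
  d <- dim(batch$fixed)
  x <- array(0, c(d[1], d[2], 2L, d[3]))
  x[, , 1, ] <- batch$fixed
  x[, , 2, ] <- batch$moving
  flow <- netForward(weights, x, train = FALSE)$flow
  warped <- warpBatch(batch$moving, flow)
  loss <- 0
  for (i in seq_len(d[3]))
    loss <- loss + simLoss(batch$fixed[, , i], warped[, , i], config$loss)
  loss / d[3] + config$loss$lambda *
    smoothnessBatch(flow)$loss
}

# Mean cord tSNR of the corrected validation runs (subsampled in time for
# speed); NA when no validation run carries a cord mask.
valTsnrMetric <- function(weights, runs, gen, config, maxVolumes = 24L) {
  vruns <- Filter(function(r) r$subject %in% gen$valSubjects &&
                    !is.null(r$cordMask), runs)
  if (length(vruns) == 0) return(NA_real_)
  vals <- vapply(vruns, function(r) {
    s <- r$series
    nt <- dim(s@data)[4]
    keep <- unique(round(seq(1, nt, length.out = min(nt, maxVolumes))))
    sub <- initialize(s, data = s@data[, , , keep, drop = FALSE])
    cor <- correctSeries(sub, weights, config$referencePolicy)
    tsnr(cor$series, r$cordMask)$mean
  }, numeric(1))
  mean(vals)
}

#' Train the registration network
#'
#' Minimizes the expected unsupervised loss over sampled slice pairs with
#' Adam. Per epoch, records the training loss, a validation loss, and the
#' cord tSNR of corrected validation data; the returned weights are those
#' of the epoch with the best validation tSNR (validation loss as
#' tie-break, or as the criterion when no cord mask is available).
#'
#' @param runs list of [fmriRun()] (min-max normalized; centerline-realigned
#'   unless that stage is disabled)
#' @param spec a [ModelSpec-class]
#' @param config a [trainConfig()]
#' @param verbose print per-epoch progress
#' @return list with `weights` ([ModelWeights-class]) and `history`
#'   (data.frame: epoch, trainLoss, valLoss, valTsnr)
#' @export
trainModel <- function(runs, spec, config = trainConfig(), verbose = FALSE) {
  for (r in runs)
    if (r$series@normalized != "minmax")
      stop("all runs must be min-max normalized before training")
  gen <- makePairGenerator(runs, config)
  weights <- buildModel(spec, seed = config$seed)
  state <- adamInit(weights@params)
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric(), valTsnr = numeric())
  best <- list(metric = -Inf, loss = Inf, weights = weights)
  tglob <- 0L
  for (ep in seq_len(config$epochs)) {
    epLoss <- 0
    for (st in seq_len(config$stepsPerEpoch)) {
      batch <- gen$nextBatch(config$batchSize, "train")
      stp <- trainStep(weights, batch, config)
      if (!is.finite(stp$loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             ", step ", st)
      tglob <- tglob + 1L
      upd <- adamStep(stp$weights@params, stp$grads, state,
                      config$learningRate, tglob)
      weights <- stp$weights
      weights@params <- upd$params
      state <- upd$state
      epLoss <- epLoss + stp$loss
    }
    vb <- gen$nextBatch(min(config$batchSize, 32L), "val")
    vloss <- evalLoss(weights, vb, config)
    vtsnr <- valTsnrMetric(weights, runs, gen, config)
    hist <- rbind(hist, data.frame(epoch = ep,
                                   trainLoss = epLoss / config$stepsPerEpoch,
                                   valLoss = vloss, valTsnr = vtsnr))
    metric <- if (is.na(vtsnr)) -vloss else vtsnr
    if (metric > best$metric ||
        (metric == best$metric && vloss < best$loss)) {
      best <- list(metric = metric, loss = vloss, weights = weights)
    }
    if (verbose)
      message(sprintf("epoch %d: train %.4f, val %.4f, val tSNR %.3f",
                      ep, epLoss / config$stepsPerEpoch, vloss, vtsnr))
  }
  list(weights = best$weights, history = hist)
}

# symmetric edge-pad a (nx, ny) slice stack to multiples of 2^depth
padPlan <- function(n, div) {
  r <- (div - n %% div) %% div
  c(lo = r %/% 2, hi = r - r %/% 2)
}

#' Correct a full 4D series with trained weights
#'
#' For every slice and volume, predicts the displacement field against the
#' reference slice and warps the moving image; the reference volume passes
#' through its own (near-identity) predicted field for uniformity. Spatial
#' dims not divisible by 2^depth are symmetrically edge-padded for
#' prediction and cropped back afterwards.
#'
#' @param series a min-max normalized [VolumeSeries-class]
#' @param weights a trained [ModelWeights-class]
#' @param referencePolicy reference-volume policy (default `"first"`)
#' @param batchSize volumes per forward pass (default 16)
#' @return list with `series` (corrected [VolumeSeries-class]) and `fields`
#'   ((nx, ny, 2, nz, nt) predicted sampling fields)
#' @export
correctSeries <- function(series, weights,
                          referencePolicy = c("first", "mid", "mean"),
                          batchSize = 16L) {
  referencePolicy <- match.arg(referencePolicy)
  if (series@normalized != "minmax")
    stop("series must be min-max normalized before correction")
  d <- series@data
  dm <- dim(d)
  depth <- length(weights@spec@encoderChannels)
  div <- 2^depth
  px <- padPlan(dm[1], div); py <- padPlan(dm[2], div)
  ix <- c(rep(1L, px["lo"]), seq_len(dm[1]), rep(dm[1], px["hi"]))
  iy <- c(rep(1L, py["lo"]), seq_len(dm[2]), rep(dm[2], py["hi"]))
  H <- length(ix); W <- length(iy)
  ref <- selectReference(series, referencePolicy)
  out <- d
  fields <- array(0, c(dm[1], dm[2], 2, dm[3], dm[4]))
  cropx <- px["lo"] + seq_len(dm[1]); cropy <- py["lo"] + seq_len(dm[2])
  for (z in seq_len(dm[3])) {
    fslice <- ref[ix, iy, z]
    for (t0 in seq(1, dm[4], by = batchSize)) {
      ts <- t0:min(dm[4], t0 + batchSize - 1L)
      n <- length(ts)
      x <- array(0, c(H, W, 2, n))
      mov <- array(0, c(H, W, n))
      for (i in seq_len(n)) {
        m <- d[ix, iy, z, ts[i]]
        x[, , 1, i] <- fslice
        x[, , 2, i] <- m
        mov[, , i] <- m
      }
      flow <- netForward(weights, x, train = FALSE)$flow
      warped <- warpBatch(mov, flow)
      for (i in seq_len(n)) {
        out[, , z, ts[i]] <- warped[cropx, cropy, i]
        fields[, , , z, ts[i]] <- flow[cropx, cropy, , i]
      }
    }
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  list(series = initialize(series, data = out), fields = fields)
}
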