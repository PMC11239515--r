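# Encoder-decoder CNN predicting a dense 2-component in-plane displacement
# field from the channel-concatenated (fixed, moving) slice pair. UNet-style:
# stride-2 3x3 convolutions down, nearest-neighbor x2 upsampling with
# skip-concatenation and 3x3 convolutions up, optional full-resolution
# refinement layers, then a linear 2-channel flow layer initialized near
# zero so the starting map is near-identity. Leaky-ReLU activations and
# batch normalization throughout (except the flow layer). Forward and
# backward passes are hand-written; convolutions run through im2col + GEMM
# in compiled code.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' Architecture presets
#'
#' `"drm1"` is the larger preset (double widths, two refinement layers);
#' `"drm2"` the compact one. Exact per-layer widths are the package's own
#' plan in the established dense-displacement-registration style; the
#' relative capacities (drm1 strictly larger, longer refinement tail) are
#' the architectural contract.
#'
#' @param preset `"drm1"` or `"drm2"`
#' @param slope leaky-ReLU negative slope
#' @param batchNorm enable batch normalization (default TRUE)
#' @return a [ModelSpec-class]
#' @export
modelSpec <- function(preset = c("drm2", "drm1"), slope = 0.2,
                      batchNorm = TRUE) {
  preset <- match.arg(preset)
  if (preset == "drm1")
    new("ModelSpec", preset = "drm1",
        encoderChannels = c(32, 64, 64, 64),
        decoderChannels = c(64, 64, 64, 64),
        refineChannels = c(32, 16), slope = slope, batchNorm = batchNorm)
  else
    new("ModelSpec", preset = "drm2",
        encoderChannels = c(16, 32, 32, 32),
        decoderChannels = c(32, 32, 32, 32),
        refineChannels = 16, slope = slope, batchNorm = batchNorm)
}

# Ordered layer plan: list of (cin, cout, stride, bn, act, role)
layerPlan <- function(spec) {
  enc <- spec@encoderChannels
  dec <- spec@decoderChannels
  depth <- length(enc)
  plan <- list()
  cin <- 2
  for (i in seq_len(depth)) {
    plan[[length(plan) + 1L]] <- list(cin = cin, cout = enc[i], stride = 2L,
                                      bn = spec@batchNorm, act = TRUE,
                                      role = paste0("enc", i))
    cin <- enc[i]
  }
  skip <- c(rev(enc[-depth]), 2)   # e.g. e3, e2, e1, input
  for (i in seq_len(depth)) {
    plan[[length(plan) + 1L]] <- list(cin = cin + skip[i], cout = dec[i],
                                      stride = 1L, bn = spec@batchNorm,
                                      act = TRUE, role = paste0("dec", i))
    cin <- dec[i]
  }
  for (j in seq_along(spec@refineChannels)) {
    plan[[length(plan) + 1L]] <- list(cin = cin,
                                      cout = spec@refineChannels[j],
                                      stride = 1L, bn = spec@batchNorm,
                                      act = TRUE, role = paste0("refine", j))
    cin <- spec@refineChannels[j]
  }
  plan[[length(plan) + 1L]] <- list(cin = cin, cout = 2L, stride = 1L,
                                    bn = FALSE, act = FALSE, role = "flow")
  plan
}

#' Build a model: deterministic initialization under a seed
#'
#' He-normal weight initialization for all convolutions; the flow layer is
#' drawn at tiny scale (sd 1e-3) with zero bias so the untrained network
#' predicts a near-zero field.
#'
#' @param spec a [ModelSpec-class]
#' @param seed initialization seed
#' @return a [ModelWeights-class]
#' @export
buildModel <- function(spec, seed = 1) {
  stopifnot(is(spec, "ModelSpec"))
  env <- new.env(); env$seed <- deriveSeed(seed, "init")
  plan <- layerPlan(spec)
  params <- withRngStream(env, lapply(plan, function(ly) {
    sdw <- if (ly$role == "flow") 1e-3 else sqrt(2 / (9 * ly$cin))
    p <- list(W = array(rnorm(9 * ly$cin * ly$cout, 0, sdw),
                        c(3, 3, ly$cin, ly$cout)),
              b = numeric(ly$cout),
              stride = ly$stride, bn = ly$bn, act = ly$act, role = ly$role)
    if (ly$bn) {
      p$gamma <- rep(1, ly$cout); p$beta <- numeric(ly$cout)
      p$rmean <- numeric(ly$cout); p$rvar <- rep(1, ly$cout)
    }
    p
  }))
  new("ModelWeights", params = params, spec = spec, seed = seed)
}

#' Number of trainable parameters
#' @param weights a [ModelWeights-class]
#' @return integer count (conv weights, biases, BN scales and offsets)
#' @export
parameterCount <- function(weights) {
  sum(vapply(weights@params, function(p) {
    length(p$W) + length(p$b) +
      (if (!is.null(p$gamma)) length(p$gamma) + length(p$beta) else 0L)
  }, numeric(1)))
}

checkDivisible <- function(H, W, depth) {
  div <- 2^depth
  if (H %% div != 0 || W %% div != 0)
    stop("spatial dims ", H, "x", W, " must be divisible by ", div,
         " (2^encoder depth)")
}

# ---- batch-norm forward/backward over (H, W, C, N), stats per channel ------
# Arrays are viewed as (H*W) x (C*N) matrices in place (no aperm copies);
# per-channel statistics pool the N columns belonging to each channel.

perChannel <- function(colstat, C, N) .rowMeans(matrix(colstat, C, N), C, N)

bnFwd <- function(z, p, train) {
  d <- dim(z)
  C <- d[3]; N <- d[4]; M <- d[1] * d[2]
  dim(z) <- c(M, C * N)
  if (train) {
    cm <- .colMeans(z, M, C * N)
    cm2 <- .colMeans(z * z, M, C * N)
    mu <- perChannel(cm, C, N)
    va <- perChannel(cm2, C, N) - mu^2
    p$rmean <- BN_MOMENTUM * p$rmean + (1 - BN_MOMENTUM) * mu
    p$rvar <- BN_MOMENTUM * p$rvar + (1 - BN_MOMENTUM) * va
  } else {
    mu <- p$rmean; va <- p$rvar
  }
  ivar <- 1 / sqrt(va + BN_EPS)
  muCol <- rep(mu, N); ivCol <- rep(ivar, N)
  xhat <- (z - rep(muCol, each = M)) * rep(ivCol, each = M)
  y <- xhat * rep(rep(p$gamma, N), each = M) +
    rep(rep(p$beta, N), each = M)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, ivar = ivar, d = d), p = p)
}

bnBwd <- function(gy, p, cache) {
  d <- cache$d
  C <- d[3]; N <- d[4]; M <- d[1] * d[2]
  dim(gy) <- c(M, C * N)
  xhat <- cache$xhat
  dgamma <- rowSums(matrix(.colSums(gy * xhat, M, C * N), C, N))
  dbeta <- rowSums(matrix(.colSums(gy, M, C * N), C, N))
  dxhat <- gy * rep(rep(p$gamma, N), each = M)
  mdx <- perChannel(.colMeans(dxhat, M, C * N), C, N)
  mdxx <- perChannel(.colMeans(dxhat * xhat, M, C * N), C, N)
  dz <- (dxhat - rep(rep(mdx, N), each = M) -
           xhat * rep(rep(mdxx, N), each = M)) *
    rep(rep(cache$ivar, N), each = M)
  dim(dz) <- d
  list(gz = dz, dgamma = dgamma, dbeta = dbeta)
}

# ---- single conv layer (conv -> BN -> leaky ReLU) --------------------------

layerFwd <- function(x, p, slope, train) {
  z <- .conv2dFwd(x, p$W, p$b, p$stride)
  cache <- list(x = x)
  if (p$bn) {
    r <- bnFwd(z, p, train)
    z <- r$y; cache$bn <- r$cache; p <- r$p
  }
  if (p$act) {
    scale <- slope + (1 - slope) * (z > 0)
    z <- z * scale
    cache$scale <- scale
  }
  list(y = z, cache = cache, p = p)
}

layerBwd <- function(gy, p, cache, slope) {
  if (p$act) {
    gy <- gy * cache$scale
  }
  g <- list()
  if (p$bn) {
    r <- bnBwd(gy, p, cache$bn)
    gy <- r$gz; g$dgamma <- r$dgamma; g$dbeta <- r$dbeta
  }
  cb <- .conv2dBwd(cache$x, p$W, gy, p$stride)
  g$dW <- cb$gw; g$db <- cb$gb
  list(gx = cb$gx, g = g)
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

downsampleSum <- function(g) {
  d <- dim(g)
  o1 <- seq(1, d[1], 2); o2 <- seq(2, d[1], 2)
  p1 <- seq(1, d[2], 2); p2 <- seq(2, d[2], 2)
  g[o1, p1, , , drop = FALSE] + g[o2, p1, , , drop = FALSE] +
    g[o1, p2, , , drop = FALSE] + g[o2, p2, , , drop = FALSE]
}

concatC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Forward pass over a batch x: (H, W, 2, N). Returns flow (H, W, 2, N),
# caches for backprop, and weights with updated BN running stats.
netForward <- function(weights, x, train = FALSE) {
  spec <- weights@spec
  params <- weights@params
  depth <- length(spec@encoderChannels)
  checkDivisible(dim(x)[1], dim(x)[2], depth)
  slope <- spec@slope
  caches <- vector("list", length(params))
  acts <- vector("list", depth)   # encoder outputs for skips
  h <- x
  li <- 0L
  for (i in seq_len(depth)) {
    li <- li + 1L
    r <- layerFwd(h, params[[li]], slope, train)
    h <- r$y; caches[[li]] <- r$cache; params[[li]] <- r$p
    acts[[i]] <- h
  }
  skips <- c(rev(acts[-depth]), list(x))
  for (i in seq_len(depth)) {
    li <- li + 1L
    cc <- concatC(upsample2(h), skips[[i]])
    r <- layerFwd(cc, params[[li]], slope, train)
    h <- r$y; caches[[li]] <- r$cache; params[[li]] <- r$p
  }
  while (li < length(params)) {
    li <- li + 1L
    r <- layerFwd(h, params[[li]], slope, train)
    h <- r$y; caches[[li]] <- r$cache; params[[li]] <- r$p
  }
  weights@params <- params
  list(flow = h, caches = caches, weights = weights)
}

# Backward pass: gflow has the flow's shape. Returns per-layer gradients.
netBackward <- function(weights, caches, gflow) {
  spec <- weights@spec
  params <- weights@params
  depth <- length(spec@encoderChannels)
  slope <- spec@slope
  nl <- length(params)
  grads <- vector("list", nl)
  g <- gflow
  # flow + refine layers (straight chain)
  for (li in nl:(2 * depth + 1)) {
    r <- layerBwd(g, params[[li]], caches[[li]], slope)
    grads[[li]] <- r$g
    g <- r$gx
  }
  # decoder: split concat gradient into upsample path and skip path
  encCh <- spec@encoderChannels
  skipCh <- c(rev(encCh[-depth]), 2)
  gskips <- vector("list", depth)
  for (i in depth:1) {
    li <- depth + i
    r <- layerBwd(g, params[[li]], caches[[li]], slope)
    grads[[li]] <- r$g
    gcc <- r$gx
    cu <- dim(gcc)[3] - skipCh[i]
    gup <- gcc[, , seq_len(cu), , drop = FALSE]
    gskips[[i]] <- gcc[, , cu + seq_len(skipCh[i]), , drop = FALSE]
    g <- downsampleSum(gup)
  }
  # encoder: g currently holds the gradient at enc[depth]'s output
  for (i in depth:1) {
    # skip contributions: decoder stage (depth - i) consumed enc i's output
    j <- depth - i
    if (j >= 1 && j <= depth - 1) g <- g + gskips[[j]]
    r <- layerBwd(g, params[[i]], caches[[i]], slope)
    grads[[i]] <- r$g
    g <- r$gx
  }
  grads
}

#' Predict a displacement field for one slice pair
#'
#' @param weights a (possibly trained) [ModelWeights-class]
#' @param fixed,moving 2D matrices normalized to [0, 1], equal shapes,
#'   dims divisible by 2^depth
#' @return an (nx, ny, 2) displacement field in voxels
#' @export
predictField <- function(weights, fixed, moving) {
  stopifnot(is(weights, "ModelWeights"))
  if (!all(dim(fixed) == dim(moving))) stop("fixed/moving shape mismatch")
  rng <- range(fixed, moving)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("inputs must be min-max normalized to [0, 1]")
  x <- array(c(fixed, moving), c(dim(fixed), 2L, 1L))
  flow <- netForward(weights, x, train = FALSE)$flow
  if (any(!is.finite(flow))) stop("predicted field contains non-finite values")
  array(flow, c(dim(fixed), 2L))
}

# ---- Adam ------------------------------------------------------------------

adamInit <- function(params) {
  lapply(params, function(p) {
    s <- list(mW = array(0, dim(p$W)), vW = array(0, dim(p$W)),
              mb = numeric(length(p$b)), vb = numeric(length(p$b)))
    if (!is.null(p$gamma)) {
      s$mg <- numeric(length(p$gamma)); s$vg <- s$mg
      s$mB <- s$mg; s$vB <- s$mg
    }
    s
  })
}

adamUpdate1 <- function(theta, g, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adamStep <- function(params, grads, state, lr, t) {
  for (i in seq_along(params)) {
    u <- adamUpdate1(params[[i]]$W, grads[[i]]$dW,
                     state[[i]]$mW, state[[i]]$vW, lr, t)
    params[[i]]$W <- u$theta; state[[i]]$mW <- u$m; state[[i]]$vW <- u$v
    u <- adamUpdate1(params[[i]]$b, grads[[i]]$db,
                     state[[i]]$mb, state[[i]]$vb, lr, t)
    params[[i]]$b <- u$theta; state[[i]]$mb <- u$m; state[[i]]$vb <- u$v
    if (!is.null(params[[i]]$gamma)) {
      u <- adamUpdate1(params[[i]]$gamma, grads[[i]]$dgamma,
                       state[[i]]$mg, state[[i]]$vg, lr, t)
      params[[i]]$gamma <- u$theta; state[[i]]$mg <- u$m; state[[i]]$vg <- u$v
      u <- adamUpdate1(params[[i]]$beta, grads[[i]]$dbeta,
                       state[[i]]$mB, state[[i]]$vB, lr, t)
      params[[i]]$beta <- u$theta; state[[i]]$mB <- u$m; state[[i]]$vB <- u$v
    }
  }
  list(params = params, state = state)
}

#' Save / load model weights
#'
#' Weights are stored as an RDS checkpoint accompanied by a JSON sidecar
#' recording the architecture preset and seeds; loading verifies the sidecar
#' matches the checkpoint's spec.
#'
#' @param weights a [ModelWeights-class]
#' @param path checkpoint path (`.rds`); the sidecar is `path.json`
#' @return `saveModelWeights`: invisibly, the path; `loadModelWeights`:
#'   the [ModelWeights-class]
#' @export
saveModelWeights <- function(weights, path) {
  saveRDS(weights, path)
  sidecar <- list(preset = weights@spec@preset,
                  encoderChannels = weights@spec@encoderChannels,
                  decoderChannels = weights@spec@decoderChannels,
                  refineChannels = weights@spec@refineChannels,
                  seed = weights@seed,
                  parameters = parameterCount(weights))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModelWeights
#' @export
loadModelWeights <- function(path) {
  w <- readRDS(path)
  if (!is(w, "ModelWeights")) stop("not a ModelWeights checkpoint: ", path)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!identical(side$preset, w@spec@preset))
      stop("checkpoint/sidecar preset mismatch for ", path)
  }
  w
}
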