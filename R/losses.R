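# Unsupervised objective: L = L_sim + lambda * L_reg, with L_sim either
# mean squared error or locally windowed (squared) normalized
# cross-correlation, and L_reg a forward-difference gradient penalty on the
# displacement field. All reductions are means, so lambda transfers across
# image sizes. Analytic gradients accompany every term.

#' Loss configuration
#'
#' @param sim similarity term: `"ncc"` (windowed normalized cross-correlation,
#'   the default the full pipeline trains with) or `"mse"`
#' @param lambda non-negative regularization weight on the smoothness term;
#'   default 0.01, the value at which validation tSNR peaks
#' @param nccWindow odd window side n for the local correlation (default 3)
#' @param imageSigma intensity scale sigma in the MSE term (default 1)
#' @param eps stabilizer added to the NCC denominator (default 1e-5)
#' @return a list of class `LossConfig`
#' @export
lossConfig <- function(sim = c("ncc", "mse"), lambda = 0.01, nccWindow = 3,
                       imageSigma = 1, eps = 1e-5) {
  sim <- match.arg(sim)
  stopifnot(lambda >= 0, nccWindow >= 1, nccWindow %% 2 == 1, eps > 0,
            imageSigma > 0)
  structure(list(sim = sim, lambda = lambda, nccWindow = as.integer(nccWindow),
                 imageSigma = imageSigma, eps = eps), class = "LossConfig")
}

checkShapes <- function(f, w) {
  if (!all(dim(f) == dim(w)))
    stop("shape mismatch: fixed is ", paste(dim(f), collapse = "x"),
         ", warped is ", paste(dim(w), collapse = "x"))
}

#' Mean squared error similarity
#'
#' `(1 / sigma^2) * mean((F - W)^2)` over all pixels.
#'
#' @param fixed,warped 2D matrices of equal shape (warped = already-warped
#'   moving image)
#' @param config a [lossConfig()]
#' @return scalar loss (>= 0; 0 iff the images are identical)
#' @export
mseLoss <- function(fixed, warped, config = lossConfig("mse")) {
  checkShapes(fixed, warped)
  mean((fixed - warped)^2) / config$imageSigma^2
}

mseGrad <- function(fixed, warped, config) {
  2 * (warped - fixed) / (length(fixed) * config$imageSigma^2)
}

# Window statistics shared by the NCC value and gradient.
nccParts <- function(fixed, warped, config) {
  n2 <- config$nccWindow^2
  SF <- .boxSum(fixed, config$nccWindow)
  SW <- .boxSum(warped, config$nccWindow)
  SFF <- .boxSum(fixed^2, config$nccWindow)
  SWW <- .boxSum(warped^2, config$nccWindow)
  SFW <- .boxSum(fixed * warped, config$nccWindow)
  a <- SFW - SF * SW / n2
  b <- SFF - SF^2 / n2
  cc <- SWW - SW^2 / n2
  list(a = a, b = b, cc = cc, SF = SF, SW = SW, n2 = n2,
       den = b * cc + config$eps)
}

#' Windowed normalized cross-correlation similarity
#'
#' At every pixel p the squared Pearson correlation of the two images over
#' the n-by-n window centered at p (windows edge-clamped) is computed; the
#' loss is minus their mean, so perfectly (affinely) matched images score -1
#' and unrelated images score near 0. Lower is better, uniformly with the
#' other losses.
#'
#' @inheritParams mseLoss
#' @return scalar loss in [-1, 0]
#' @export
nccLoss <- function(fixed, warped, config = lossConfig("ncc")) {
  checkShapes(fixed, warped)
  p <- nccParts(fixed, warped, config)
  -mean(p$a^2 / p$den)
}

nccGrad <- function(fixed, warped, config) {
  p <- nccParts(fixed, warped, config)
  N <- length(fixed)
  A <- -(2 / N) * p$a / p$den               # dL/da(p)
  Cc <- (1 / N) * p$a^2 * p$b / p$den^2     # dL/dc(p)
  fixed * .boxSumAdj(A, config$nccWindow) +
    2 * warped * .boxSumAdj(Cc, config$nccWindow) +
    .boxSumAdj(-A * p$SF / p$n2 - 2 * Cc * p$SW / p$n2, config$nccWindow)
}

simLoss <- function(fixed, warped, config) {
  if (config$sim == "mse") mseLoss(fixed, warped, config)
  else nccLoss(fixed, warped, config)
}

simGrad <- function(fixed, warped, config) {
  if (config$sim == "mse") mseGrad(fixed, warped, config)
  else nccGrad(fixed, warped, config)
}

#' Displacement-field smoothness penalty
#'
#' Squared forward differences of each field component along each in-plane
#' axis; each of the four difference sets is averaged over its own valid
#' positions and the four means are summed. Adding a constant vector to the
#' field leaves the penalty unchanged.
#'
#' @param field (nx, ny, 2) displacement array
#' @return scalar penalty (0 for a constant field)
#' @export
smoothnessLoss <- function(field) {
  if (any(!is.finite(field))) stop("field contains non-finite values")
  total <- 0
  for (k in 1:2) {
    u <- field[, , k]
    dx <- u[-1, , drop = FALSE] - u[-nrow(u), , drop = FALSE]
    dy <- u[, -1, drop = FALSE] - u[, -ncol(u), drop = FALSE]
    total <- total + mean(dx^2) + mean(dy^2)
  }
  total
}

smoothnessGrad <- function(field) {
  g <- array(0, dim(field))
  for (k in 1:2) {
    u <- field[, , k]
    dx <- u[-1, , drop = FALSE] - u[-nrow(u), , drop = FALSE]
    dy <- u[, -1, drop = FALSE] - u[, -ncol(u), drop = FALSE]
    gk <- matrix(0, nrow(u), ncol(u))
    cx <- 2 / length(dx); cy <- 2 / length(dy)
    gk[-1, ] <- gk[-1, ] + cx * dx
    gk[-nrow(u), ] <- gk[-nrow(u), ] - cx * dx
    gk[, -1] <- gk[, -1] + cy * dy
    gk[, -ncol(u)] <- gk[, -ncol(u)] - cy * dy
    g[, , k] <- gk
  }
  g
}

#' Total registration loss
#'
#' `simLoss(fixed, warp(moving, field)) + lambda * smoothnessLoss(field)`.
#'
#' @param fixed,moving 2D matrices of equal shape
#' @param field (nx, ny, 2) displacement array
#' @param config a [lossConfig()]
#' @return scalar loss
#' @export
totalLoss <- function(fixed, moving, field, config = lossConfig()) {
  checkShapes(fixed, moving)
  warped <- warpSlice(moving, field)
  simLoss(fixed, warped, config) + config$lambda * smoothnessLoss(field)
}

#' Gradient of the total loss with respect to the field
#'
#' Chains the similarity gradient through the warper's adjoint and adds the
#' smoothness gradient. This is the quantity gradient-based training
#' descends on (through the network Jacobian).
#'
#' @inheritParams totalLoss
#' @return (nx, ny, 2) gradient array
#' @export
totalLossGradField <- function(fixed, moving, field, config = lossConfig()) {
  warped <- warpSlice(moving, field)
  gW <- simGrad(fixed, warped, config)
  warpSliceGrad(moving, field, gW)$gfield +
    config$lambda * smoothnessGrad(field)
}

# Batched versions over (H, W, N) stacks; loss is the mean over the batch.
simLossGradBatch <- function(fixedB, warpedB, config) {
  N <- dim(fixedB)[3]
  g <- array(0, dim(fixedB))
  loss <- 0
  for (i in seq_len(N)) {
    f <- fixedB[, , i]; w <- warpedB[, , i]
    loss <- loss + simLoss(f, w, config)
    g[, , i] <- simGrad(f, w, config) / N
  }
  list(loss = loss / N, grad = g)
}

smoothnessBatch <- function(fieldB) {
  N <- dim(fieldB)[4]
  loss <- 0
  g <- array(0, dim(fieldB))
  for (i in seq_len(N)) {
    loss <- loss + smoothnessLoss(fieldB[, , , i])
    g[, , , i] <- smoothnessGrad(fieldB[, , , i]) / N
  }
  list(loss = loss / N, grad = g)
}
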