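# Internal helpers: deterministic seed fan-out and isolated RNG streams.

# One global seed fans out to named substreams so that phantom generation,
# weight initialization and pair sampling draw from independent,
# reproducible sequences. Kept below 2^31 - 1.
deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Evaluate expr under its own RNG state stored in `env$rngState`, without
# disturbing the caller's RNG.
withRngStream <- function(env, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  if (is.null(env$rngState)) set.seed(env$seed)
  else assign(".Random.seed", env$rngState, globalenv())
  res <- force(expr)
  env$rngState <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  res
}

# Separable Gaussian blur of a matrix with edge replication, implemented as
# banded matrix products (exact, no FFT edge effects).
gaussBlurMat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  blur1 <- function(n) {
    half <- max(1L, ceiling(3 * sigma))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmin(pmax(i + (-half:half), 1L), n)
      w <- exp(-((-half:half)^2) / (2 * sigma^2))
      for (k in seq_along(j)) K[i, j[k]] <- K[i, j[k]] + w[k]
    }
    K / rowSums(K)
  }
  Kx <- blur1(nrow(m)); Ky <- blur1(ncol(m))
  Kx %*% m %*% t(Ky)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
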