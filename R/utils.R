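# Internal helpers.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Separable Gaussian smoothing of a matrix, kernel truncated at 4 sigma,
# edge-renormalised (each output cell is a weighted mean of in-grid cells).
gaussSmooth <- function(x, sigmaCells) {
  if (sigmaCells <= 0) return(x)
  r <- max(1L, ceiling(4 * sigmaCells))
  k <- stats::dnorm(seq(-r, r), sd = sigmaCells)
  smooth1 <- function(m) {
    # band matrix B with B[i, j] = k[|i - j| + r + 1], rows renormalised
    n <- nrow(m)
    idx <- abs(outer(seq_len(n), seq_len(n), "-"))
    B <- matrix(0, n, n)
    within <- idx <= r
    B[within] <- k[idx[within] + 1L]
    B <- B / rowSums(B)
    B %*% m
  }
  x <- smooth1(x)
  t(smooth1(t(x)))
}

# Rescale a matrix affinely so its range is exactly [lo, hi]; a constant
# matrix (e.g. a 1 x 1 grid) maps to the interval midpoint.
rescaleTo <- function(x, lo, hi) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0) {
    x[] <- (lo + hi) / 2
    return(x)
  }
  lo + (x - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}
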