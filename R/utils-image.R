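# Small image-processing primitives shared by the renderer and the
# orientation estimator: separable Gaussian convolution with replicate
# padding, built on stats::filter (which runs down the columns of a matrix).

gauss_kernel <- function(sigma, radius = NULL) {
  if (sigma <= 0) return(1)
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k / sum(k)
}

# Convolve along dim 1 (down each column) with replicate padding.
conv_cols <- function(m, k) {
  if (length(k) == 1L) return(m * k)
  p <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  mp <- rbind(m[rep(1L, p), , drop = FALSE], m,
              m[rep(n, p), , drop = FALSE])
  f <- stats::filter(mp, k, sides = 2)
  matrix(f[(p + 1L):(p + n), ], n, ncol(m))
}

# Separable Gaussian blur of a matrix (sigmas in pixels, per dimension).
gauss_blur_2d <- function(m, sigma1, sigma2 = sigma1) {
  m <- conv_cols(m, gauss_kernel(sigma1))
  t(conv_cols(t(m), gauss_kernel(sigma2)))
}

# Separable Gaussian blur of a 3D array (sigmas in voxels, per dimension).
gauss_blur_3d <- function(a, sigma) {
  d <- dim(a)
  if (sigma[1] > 0) {
    a <- array(conv_cols(matrix(a, d[1], d[2] * d[3]), gauss_kernel(sigma[1])), d)
  }
  if (sigma[2] > 0) {
    a <- aperm(a, c(2, 1, 3))
    a <- array(conv_cols(matrix(a, d[2], d[1] * d[3]), gauss_kernel(sigma[2])),
               c(d[2], d[1], d[3]))
    a <- aperm(a, c(2, 1, 3))
  }
  if (sigma[3] > 0) {
    a <- aperm(a, c(3, 1, 2))
    a <- array(conv_cols(matrix(a, d[3], d[1] * d[2]), gauss_kernel(sigma[3])),
               c(d[3], d[1], d[2]))
    a <- aperm(a, c(2, 3, 1))
  }
  a
}

# Accumulate weights w at linear indices idx into a zero vector of length n.
accumulate_at <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# Run a block of code with a fixed RNG seed, restoring the caller's RNG
# state afterwards (keeps renders deterministic without clobbering the
# session RNG).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
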