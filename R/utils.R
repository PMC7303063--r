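# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  All stochastic code in the package goes through
# this so that user-level seeds are the only source of randomness.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 2-D FFT wrappers. R's fft() is multidimensional already; these only fix
# the normalization convention (unitary on the inverse).
fft2 <- function(x) stats::fft(x)
ifft2 <- function(X, real = TRUE) {
  x <- stats::fft(X, inverse = TRUE) / length(X)
  if (real) Re(x) else x
}

# Signed DFT frequency index grid for length n: 0, 1, ..., -1 (radians/sample
# after scaling by 2*pi/n).
fft_freqs <- function(n) {
  k <- 0:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  2 * pi * k / n
}

# Circularly shift a matrix by (dr, dc): result[i, j] = x[i + dr, j + dc]
# with wraparound.  Used by the autocorrelation statistics.
circ_shift <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- ((seq_len(nr) - 1L + dr) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L + dc) %% nc) + 1L
  x[ri, ci, drop = FALSE]
}

# Crop the central block of a centred spectrum.  `X` is in standard DFT
# layout (DC at [1,1]); we fftshift, crop, unshift.
fftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c((floor(nr / 2) + 1):nr, 1:floor(nr / 2)),
    c((floor(nc / 2) + 1):nc, 1:floor(nc / 2)), drop = FALSE]
}
ifftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c((ceiling(nr / 2) + 1):nr, 1:ceiling(nr / 2)),
    c((ceiling(nc / 2) + 1):nc, 1:ceiling(nc / 2)), drop = FALSE]
}

# Keep the central (nr2 x nc2) frequencies of spectrum X (DFT layout).
spec_crop <- function(X, nr2, nc2) {
  Xs <- fftshift2(X)
  nr <- nrow(X); nc <- ncol(X)
  r0 <- floor(nr / 2) - floor(nr2 / 2)
  c0 <- floor(nc / 2) - floor(nc2 / 2)
  ifftshift2(Xs[(r0 + 1):(r0 + nr2), (c0 + 1):(c0 + nc2), drop = FALSE])
}

# Zero-pad spectrum X (DFT layout) out to (nr2 x nc2).
spec_pad <- function(X, nr2, nc2) {
  Xs <- fftshift2(X)
  out <- matrix(0 + 0i, nr2, nc2)
  nr <- nrow(X); nc <- ncol(X)
  r0 <- floor(nr2 / 2) - floor(nr / 2)
  c0 <- floor(nc2 / 2) - floor(nc / 2)
  out[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc)] <- Xs
  ifftshift2(out)
}

# Downsample a matrix by 2x2 block averaging (then recurse for higher
# powers of two).  Block means preserve a partition of unity across maps.
block_mean <- function(w, fac) {
  while (fac > 1L) {
    nr2 <- 2L * (nrow(w) %/% 2L); nc2 <- 2L * (ncol(w) %/% 2L)
    w <- (w[seq(1L, nr2, 2L), seq_len(nc2), drop = FALSE] +
            w[seq(2L, nr2, 2L), seq_len(nc2), drop = FALSE]) / 2
    w <- (w[, seq(1L, nc2, 2L), drop = FALSE] +
            w[, seq(2L, nc2, 2L), drop = FALSE]) / 2
    fac <- fac %/% 2L
  }
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
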