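# Naive reference implementations used as independent oracles.  Everything
# here is written as explicit double loops over pixels so the vectorized
# package code is checked against a maximally transparent computation.

oracle_wmean <- function(x, w) {
  s <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    s <- s + w[i, j] * x[i, j]
  s
}

oracle_wmoments <- function(x, w) {
  mu <- oracle_wmean(x, w)
  m2 <- m3 <- m4 <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    d <- x[i, j] - mu
    m2 <- m2 + w[i, j] * d^2
    m3 <- m3 + w[i, j] * d^3
    m4 <- m4 + w[i, j] * d^4
  }
  # shape statistics are variance-gated and clipped, per their definition
  gate <- m2^2 / (m2^2 + 1e-10)
  c(mean = mu, var = m2,
    skew = if (m2 > 1e-18) gate * max(-10, min(10, m3 / m2^1.5)) else 0,
    kurt = if (m2 > 1e-18) gate * min(50, m4 / m2^2) else 0)
}

# weighted Pearson correlation of x with its circular shift by (dy, dx)
oracle_wautocorr <- function(x, w, dy, dx) {
  nr <- nrow(x); nc <- ncol(x)
  xd <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    xd[i, j] <- x[(i - 1 + dy) %% nr + 1, (j - 1 + dx) %% nc + 1]
  oracle_wcor(x, xd, w)
}

oracle_wcor <- function(a, b, w) {
  ma <- oracle_wmean(a, w); mb <- oracle_wmean(b, w)
  saa <- sab <- sbb <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    da <- a[i, j] - ma; db <- b[i, j] - mb
    saa <- saa + w[i, j] * da^2
    sbb <- sbb + w[i, j] * db^2
    sab <- sab + w[i, j] * da * db
  }
  if (saa <= 1e-18 || sbb <= 1e-18) return(0)
  max(-1, min(1, sab / sqrt(saa * sbb)))
}

# brute-force count of k-subsets of n items, by explicit enumeration
oracle_subset_count <- function(n, k) {
  if (k == 0 || k == n) return(1L)
  nrow(t(utils::combn(n, k)))
}

# a small smooth positive weight map covering the whole grid
oracle_weight_map <- function(nr, nc) {
  w <- outer(sin(pi * (seq_len(nr) - 0.5) / nr),
             sin(pi * (seq_len(nc) - 0.5) / nc)) + 0.2
  w / sum(w)
}
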