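# The peripheral encoding: per-region summary statistics over the oriented
# pyramid, in the texture-model family of Portilla & Simoncelli.  Groups:
#   marginal     luminance mean, variance, skewness, kurtosis, min, max
#   highpass_var variance of the highpass residual
#   autocorr     central MxM normalized autocorrelation of the luminance
#                image and of each scale's lowpass band
#   mag_acorr    same autocorrelation of each oriented band's magnitude
#   mag_ocorr    magnitude correlation across orientation pairs in a scale
#   mag_scorr    magnitude correlation across adjacent scales (coarse band
#                spectrally upsampled)
#   phase_scorr  real-part correlation of the phase-doubled coarse band
#                with the fine band
# All correlations are weighted by the region's pooling window and lie in
# [-1, 1]; correlations involving a (near) zero-variance signal are defined
# as 0 so that statistic vectors stay comparable across regions.

#' Encoder configuration
#'
#' @param S number of pyramid scales.
#' @param O number of orientations.
#' @param M odd side length of the central autocorrelation neighborhood,
#'   in band-resolution pixels.
#' @return list of class `stat_config`.
#' @export
stat_config <- function(S = 4L, O = 4L, M = 7L) {
  if (M %% 2L != 1L || M < 1L) stop("`M` must be odd and >= 1", call. = FALSE)
  if (S < 1L || O < 1L) stop("S and O must be >= 1", call. = FALSE)
  structure(list(S = as.integer(S), O = as.integer(O), M = as.integer(M)),
            class = "stat_config")
}

#' Number of statistics per pooling region
#'
#' Closed form for the length of a statistic vector:
#' \deqn{7 + S + 2 S O + (S + 1 + S O)(M^2 - 1)/2 + S O (O - 1)/2 + 2 (S - 1) O^2}
#' i.e. 6 luminance marginals + 1 highpass variance; S lowpass-band
#' variances and 2 energy statistics (magnitude mean, variance) per
#' oriented band; the unique half of the central MxM autocorrelation for
#' the luminance image, the S lowpass bands and the S*O magnitude bands
#' (autocorrelations are symmetric, so only one of each +/-offset pair is
#' counted, and the zero offset is identically 1 and not stored); all
#' within-scale orientation pairs; and O x O cross-scale magnitude and
#' phase correlations for each adjacent scale pair.  The default
#' configuration (S=4, O=4, M=7) gives 667 statistics per region, within
#' the model's nominal per-region budget of about a thousand.
#'
#' @param config a [stat_config()].
#' @return integer statistic count.
#' @export
stat_count <- function(config = stat_config()) {
  S <- config$S; O <- config$O; M <- config$M
  half <- (M^2 - 1L) %/% 2L
  as.integer(7L + S + 2L * S * O + (S + 1L + S * O) * half +
               (S * O * (O - 1L)) %/% 2L + 2L * max(0L, S - 1L) * O^2)
}

# Unique half of the central MxM offset grid (excludes (0,0) and one of
# each +/- pair).
acorr_offsets <- function(M) {
  h <- (M - 1L) %/% 2L
  if (h == 0L) return(matrix(integer(0), ncol = 2))
  g <- expand.grid(dy = -h:h, dx = -h:h)
  g <- g[g$dy > 0 | (g$dy == 0 & g$dx > 0), ]
  as.matrix(g[order(g$dy, g$dx), ])
}

EPS_VAR <- 1e-18

# Weighted Pearson correlation from raw weighted sums (weights sum to 1):
# sx = E[x], sxx = E[x^2], etc.
wcor_from_sums <- function(sx, sxx, sy, syy, sxy) {
  vx <- sxx - sx^2; vy <- syy - sy^2
  if (!is.finite(vx) || !is.finite(vy) || vx <= EPS_VAR || vy <= EPS_VAR)
    return(0)
  r <- (sxy - sx * sy) / sqrt(vx * vy)
  max(-1, min(1, r))
}

# Crop matrix `x` to a bounding box expanded by `h` with circular wrap,
# given bbox rows r0:r1, cols c0:c1 (1-based).
crop_wrap <- function(x, r0, r1, c0, c1, h) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- ((r0 - h - 1):(r1 + h - 1)) %% nr + 1L
  ci <- ((c0 - h - 1):(c1 + h - 1)) %% nc + 1L
  x[ri, ci, drop = FALSE]
}

# Weighted autocorrelation of x (Pearson of x against its circularly
# shifted self) at the given offsets. `xe` is the wrap-expanded crop, `wc`
# the weight crop (sums to 1), h the margin.
wacorr <- function(xe, wc, offs, h) {
  nr <- nrow(wc); nc <- ncol(wc)
  x0 <- xe[(h + 1):(h + nr), (h + 1):(h + nc), drop = FALSE]
  sx <- sum(wc * x0); sxx <- sum(wc * x0 * x0)
  n <- nrow(offs)
  out <- numeric(n)
  if (n == 0L) return(out)
  # gather all shifted crops into one matrix, reduce with BLAS
  V <- matrix(0, nr * nc, n)
  for (i in seq_len(n)) {
    dy <- offs[i, 1]; dx <- offs[i, 2]
    V[, i] <- xe[(h + 1 + dy):(h + nr + dy), (h + 1 + dx):(h + nc + dx)]
  }
  wv <- as.vector(wc)
  su <- crossprod(V, cbind(wv, wv * as.vector(x0)))   # E[xd], E[x*xd]
  sq <- crossprod(V * V, wv)                          # E[xd^2]
  for (i in seq_len(n))
    out[i] <- wcor_from_sums(sx, sxx, su[i, 1], sq[i], su[i, 2])
  out
}

# Weighted Pearson between two maps under weight crop wc (sums to 1).
wcor_maps <- function(a, b, wc) {
  wcor_from_sums(sum(wc * a), sum(wc * a * a), sum(wc * b),
                 sum(wc * b * b), sum(wc * a * b))
}

# Precompute every feature map the per-region statistics need.  With
# `min_fac` > 0, maps for bands finer than that dyadic factor are skipped
# (used by the coarse-scale refinement pass of mongrel synthesis).
stat_precompute <- function(pyramid, config, min_fac = 0L) {
  S <- config$S; O <- config$O
  stopifnot(pyramid$S >= S, pyramid$O == O)
  mags <- band_re <- vector("list", S)
  for (s in seq_len(S)) {
    if (s - 1L < min_fac) next
    mags[[s]] <- lapply(seq_len(O), function(o) Mod(pyramid$bands[[s]][[o]]))
    band_re[[s]] <- lapply(seq_len(O), function(o) Re(pyramid$bands[[s]][[o]]))
  }
  up_mag <- up_phd <- vector("list", max(0L, S - 1L))
  for (s in seq_len(max(0L, S - 1L))) {
    if (s - 1L < min_fac) next
    up <- lapply(seq_len(O), function(o) upsample_band(pyramid$bands[[s + 1]][[o]]))
    up_mag[[s]] <- lapply(up, Mod)
    up_phd[[s]] <- lapply(up, function(u) Re(phase_double(u)))
  }
  list(lum = pyramid$source, chain = pyramid$lowpass_chain[seq_len(S)],
       highpass = pyramid$highpass, mags = mags, band_re = band_re,
       up_mag = up_mag, up_phd = up_phd, S = S, O = O,
       offs = acorr_offsets(config$M), M = config$M, min_fac = min_fac)
}

# Weight map pyramid for one region: full-res weights block-averaged to
# each dyadic factor and renormalized to sum 1 (NULL when the region has no
# support at that resolution).
region_weight_pyr <- function(w, max_fac_log2) {
  out <- vector("list", max_fac_log2 + 1L)
  cur <- w
  for (k in 0:max_fac_log2) {
    if (k > 0) cur <- block_mean(cur, 2L)
    s <- sum(cur)
    if (s > 0) out[[k + 1L]] <- cur / s
  }
  out
}

bbox_of <- function(w, tol = 1e-12) {
  idx <- which(w > tol, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
}

# Statistics of one region from precomputed maps.  `wpyr` indexes weight
# maps by dyadic factor: wpyr[[k+1]] is at 1/2^k resolution.
#
# Support sufficiency: a correlation estimated from fewer effective samples
# than the M^2 autocorrelation neighborhood would be dominated by sampling
# noise, so statistics at any resolution where the region's effective
# sample count (1 / sum of squared normalized weights) falls below M^2 are
# defined as 0 and the region is flagged degenerate at that scale.  The
# rule depends only on the pooling geometry, so target and synthesized
# encodings zero exactly the same entries.
region_stats_from_pre <- function(pre, wpyr, config) {
  S <- pre$S; O <- pre$O; offs <- pre$offs
  h <- (config$M - 1L) %/% 2L
  min_neff <- config$M^2
  min_fac <- pre$min_fac %||% 0L
  degenerate <- FALSE

  fac_info <- lapply(seq_len(S + 1L), function(k) {
    wc <- wpyr[[k]]
    if (is.null(wc)) return(NULL)
    bb <- bbox_of(wc)
    if (is.null(bb)) return(NULL)
    wcc <- wc[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    wcc <- wcc / sum(wcc)
    list(bb = bb, w = wcc, neff = 1 / sum(wcc^2))
  })
  ok_fac <- function(fac_log2) {
    fi <- fac_info[[fac_log2 + 1L]]
    if (is.null(fi) || fi$neff < min_neff) { degenerate <<- TRUE; FALSE }
    else TRUE
  }

  stat_band <- function(x, fac_log2) {
    if (fac_log2 < min_fac || !ok_fac(fac_log2)) return(rep(0, nrow(offs)))
    fi <- fac_info[[fac_log2 + 1L]]
    xe <- crop_wrap(x, fi$bb[1], fi$bb[2], fi$bb[3], fi$bb[4], h)
    wacorr(xe, fi$w, offs, h)
  }
  pair_sums <- function(maps, fac_log2) {
    # crops of a list of maps plus the weight crop, for cross-correlations
    if (fac_log2 < min_fac || !ok_fac(fac_log2)) return(NULL)
    fi <- fac_info[[fac_log2 + 1L]]
    list(w = fi$w,
         maps = lapply(maps, function(m)
           m[fi$bb[1]:fi$bb[2], fi$bb[3]:fi$bb[4], drop = FALSE]))
  }

  # -- marginals (full resolution; skew/kurt need sufficient support too)
  if (min_fac == 0L) {
    w0 <- wpyr[[1L]]
    sup <- w0 > 1e-12
    x <- pre$lum
    mu <- sum(w0 * x)
    xc <- x - mu
    m2 <- sum(w0 * xc^2); m3 <- sum(w0 * xc^3); m4 <- sum(w0 * xc^4)
    neff0 <- { fi <- fac_info[[1L]]; if (is.null(fi)) 0 else fi$neff }
    # shape statistics explode on near-constant regions (antialiasing
    # specks), so they are clipped to sane ranges and faded out smoothly
    # as the variance vanishes
    if (m2 > EPS_VAR && neff0 >= min_neff) {
      gate <- m2^2 / (m2^2 + 1e-10)
      skew <- gate * max(-10, min(10, m3 / m2^1.5))
      kurt <- gate * min(50, m4 / m2^2)
    } else skew <- kurt <- 0
    marginal <- c(mean = mu, var = m2, skew = skew, kurt = kurt,
                  min = min(x[sup]), max = max(x[sup]))
    hpc <- pre$highpass - sum(w0 * pre$highpass)
    highpass_var <- c(hp_var = sum(w0 * hpc^2))
  } else {
    marginal <- c(mean = 0, var = 0, skew = 0, kurt = 0, min = 0, max = 0)
    w0 <- wpyr[[1L]]
    hpc <- pre$highpass - sum(w0 * pre$highpass)
    highpass_var <- c(hp_var = sum(w0 * hpc^2))
  }

  # -- band energies: lowpass variance per scale, magnitude mean/variance
  # per oriented band (the raw "pointwise multiply then pool" moments)
  wvar <- function(x, fac_log2) {
    if (fac_log2 < min_fac || !ok_fac(fac_log2)) return(c(0, 0))
    fi <- fac_info[[fac_log2 + 1L]]
    xc <- x[fi$bb[1]:fi$bb[2], fi$bb[3]:fi$bb[4], drop = FALSE]
    mu <- sum(fi$w * xc)
    c(mu, sum(fi$w * (xc - mu)^2))
  }
  lowpass_var <- vapply(seq_len(S), function(s) wvar(pre$chain[[s]], s)[2],
                        numeric(1))
  band_energy <- unlist(lapply(seq_len(S), function(s)
    unlist(lapply(seq_len(O), function(o) wvar(pre$mags[[s]][[o]], s - 1L)))))

  # -- autocorrelations: luminance + lowpass chain
  autocorr <- c(stat_band(pre$lum, 0L),
                unlist(lapply(seq_len(S), function(s) stat_band(pre$chain[[s]], s))))

  # -- magnitude autocorrelations (band s lives at factor 2^(s-1))
  mag_acorr <- unlist(lapply(seq_len(S), function(s)
    unlist(lapply(seq_len(O), function(o) stat_band(pre$mags[[s]][[o]], s - 1L)))))

  # -- orientation cross-correlations within scale
  mag_ocorr <- unlist(lapply(seq_len(S), function(s) {
    ps <- pair_sums(pre$mags[[s]], s - 1L)
    out <- numeric(O * (O - 1) / 2); i <- 0L
    for (o1 in seq_len(O - 1)) for (o2 in (o1 + 1):O) {
      i <- i + 1L
      if (!is.null(ps)) out[i] <- wcor_maps(ps$maps[[o1]], ps$maps[[o2]], ps$w)
    }
    out
  }))

  # -- cross-scale magnitude and phase correlations
  mag_scorr <- phase_scorr <- numeric(0)
  if (S > 1L) {
    mag_scorr <- unlist(lapply(seq_len(S - 1L), function(s) {
      ps <- pair_sums(c(pre$mags[[s]], pre$up_mag[[s]]), s - 1L)
      out <- numeric(O * O); i <- 0L
      for (o1 in seq_len(O)) for (o2 in seq_len(O)) {
        i <- i + 1L
        if (!is.null(ps)) out[i] <- wcor_maps(ps$maps[[o1]], ps$maps[[O + o2]], ps$w)
      }
      out
    }))
    phase_scorr <- unlist(lapply(seq_len(S - 1L), function(s) {
      ps <- pair_sums(c(pre$band_re[[s]], pre$up_phd[[s]]), s - 1L)
      out <- numeric(O * O); i <- 0L
      for (o1 in seq_len(O)) for (o2 in seq_len(O)) {
        i <- i + 1L
        if (!is.null(ps)) out[i] <- wcor_maps(ps$maps[[o1]], ps$maps[[O + o2]], ps$w)
      }
      out
    }))
  }

  structure(list(marginal = marginal, highpass_var = highpass_var,
                 lowpass_var = lowpass_var, band_energy = band_energy,
                 autocorr = autocorr, mag_acorr = mag_acorr,
                 mag_ocorr = mag_ocorr, mag_scorr = mag_scorr,
                 phase_scorr = phase_scorr),
            degenerate = degenerate, class = "stat_vector")
}

#' Summary statistics of one pooling region
#'
#' Computes the full statistic vector for a single region weight map.  The
#' weights are normalized to sum to one over their support; at each pyramid
#' scale they are block-averaged down to the band's resolution.
#'
#' @param pyramid an `oriented_pyramid` from [build_pyramid()].
#' @param weights non-negative weight matrix at source resolution.
#' @param config a [stat_config()]; its `S`, `O` must match the pyramid.
#' @return A `stat_vector`: named list of statistic groups with a
#'   `degenerate` attribute (set when the region's support is smaller than
#'   the autocorrelation neighborhood at the coarsest scale).
#' @export
compute_region_stats <- function(pyramid, weights, config = stat_config()) {
  stopifnot(inherits(pyramid, "oriented_pyramid"))
  if (!all(dim(weights) == pyramid$dims))
    stop("weight map geometry does not match the pyramid source", call. = FALSE)
  if (sum(weights) <= 0) stop("weight map has no support", call. = FALSE)
  weights <- weights / sum(weights)
  pre <- stat_precompute(pyramid, config)
  wpyr <- region_weight_pyr(weights, config$S)
  region_stats_from_pre(pre, wpyr, config)
}

#' @export
print.stat_vector <- function(x, ...) {
  cat(sprintf("<stat_vector> %d statistics%s\n", length(unlist(x)),
              if (isTRUE(attr(x, "degenerate"))) " [degenerate support]" else ""))
  invisible(x)
}

#' Flatten a statistic vector (or field) to a plain numeric vector
#' @param x a `stat_vector` or `stat_field`.
#' @param ... unused.
#' @return named numeric vector (fields: concatenated over regions,
#'   names prefixed by region id).
#' @export
as_stat_numeric <- function(x, ...) {
  if (inherits(x, "stat_vector")) {
    groups <- unclass(x)
    out <- unlist(lapply(names(groups), function(g) {
      v <- groups[[g]]
      names(v) <- paste0(g, ".", seq_along(v))
      v
    }))
    return(out)
  }
  if (inherits(x, "stat_field")) {
    out <- unlist(lapply(names(x$vectors), function(id) {
      v <- as_stat_numeric(x$vectors[[id]])
      names(v) <- paste0(id, ".", names(v))
      v
    }))
    return(out)
  }
  stop("not a stat_vector or stat_field", call. = FALSE)
}

#' Encode an image: one statistic vector per pooling region
#'
#' The peripheral encoding: builds the oriented pyramid once and computes
#' the summary-statistic vector of every region of the pooling scheme.
#' Deterministic; region evaluation order does not affect the result.
#'
#' @param image a [lum_img()].
#' @param scheme a `pooling_scheme` built on the same image geometry (built
#'   with default parameters if omitted).
#' @param config a [stat_config()].
#' @return A `stat_field`: list with `vectors` (named by region id),
#'   `global` (whole-image marginal statistics, used to seed synthesis),
#'   and `provenance`.
#' @export
compute_stat_field <- function(image, scheme = NULL, config = stat_config()) {
  stopifnot(inherits(image, "lum_img"))
  if (is.null(scheme)) scheme <- build_pooling_scheme(image)
  if (!all(scheme$dims == dim(image$pixels)))
    stop("pooling scheme geometry does not match the image", call. = FALSE)
  pyr <- build_pyramid(image, S = config$S, O = config$O)
  pre <- stat_precompute(pyr, config)
  vectors <- vector("list", length(scheme$weights))
  names(vectors) <- scheme$regions$id
  for (i in seq_along(scheme$weights)) {
    w <- scheme$weights[[i]]
    wpyr <- region_weight_pyr(w / sum(w), config$S)
    vectors[[i]] <- region_stats_from_pre(pre, wpyr, config)
  }
  x <- image$pixels
  mu <- mean(x); xc <- x - mu
  m2 <- mean(xc^2)
  global <- c(mean = mu, var = m2,
              skew = if (m2 > EPS_VAR) mean(xc^3) / m2^1.5 else 0,
              kurt = if (m2 > EPS_VAR) mean(xc^4) / m2^2 else 0,
              min = min(x), max = max(x))
  structure(list(vectors = vectors, global = global,
                 provenance = list(config = config,
                                   scheme_params = scheme$params,
                                   dims = dim(x), ppd = image$ppd,
                                   fixation = image$fixation)),
            class = "stat_field")
}

#' @export
print.stat_field <- function(x, ...) {
  cat(sprintf("<stat_field> %d regions x %d statistics\n",
              length(x$vectors), stat_count(x$provenance$config)))
  invisible(x)
}

#' Export per-region scalar summaries to CSV
#'
#' Writes one row per region with the marginal statistics and the mean of
#' each correlation group.
#' @param field a `stat_field`.
#' @param path output CSV path.
#' @export
write_stat_csv <- function(field, path) {
  rows <- lapply(names(field$vectors), function(id) {
    v <- field$vectors[[id]]
    data.frame(region = id, t(v$marginal), hp_var = unname(v$highpass_var),
               autocorr_mean = mean(v$autocorr),
               mag_acorr_mean = mean(v$mag_acorr),
               mag_ocorr_mean = mean(v$mag_ocorr),
               mag_scorr_mean = if (length(v$mag_scorr)) mean(v$mag_scorr) else NA,
               phase_scorr_mean = if (length(v$phase_scorr)) mean(v$phase_scorr) else NA)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
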