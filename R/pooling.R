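# Eccentricity-scaled tiling of the visual field.
#
# Pooling regions grow linearly with eccentricity: nominal diameter
# d(e) = max(d0, g * e).  Linear growth in eccentricity is constant width
# in log-eccentricity, so the lattice is log-polar: raised-cosine-squared
# windows with 50% overlap in log2(e), crossed with raised-cosine-squared
# angular sectors.  cos^2 windows at 50% overlap sum exactly to one along
# each axis, and the product lattice inherits the property; a final
# pixelwise normalization guards the partition of unity at the foveal and
# outer boundaries.

# Radial window spacing in log2(e) that realizes diameter growth rate g:
# a window centred at e spans [e*2^-D, e*2^D], so g = 2^D - 2^-D.
radial_log_spacing <- function(g) log2((g + sqrt(g^2 + 4)) / 2)

cos2_win <- function(t, halfwidth) {
  w <- numeric(length(t))
  inside <- abs(t) < halfwidth
  w[inside] <- cos(pi * t[inside] / (2 * halfwidth))^2
  w
}

#' Build an eccentricity-scaled pooling scheme
#'
#' Tiles the image with smooth, overlapping pooling regions whose nominal
#' diameter grows linearly with eccentricity, `d(e) = max(d0, g * e)`:
#' a foveal disk of diameter `d0` surrounded by a log-polar lattice of
#' radial-annular sectors with cosine-squared cross-fade and 50% overlap.
#' Region weights form a partition of unity: at every pixel the weights of
#' all covering regions sum to one.
#'
#' @param image a [lum_img()] supplying geometry (ppd, fixation).
#' @param g growth rate of pooling diameter with eccentricity
#'   (dimensionless; 0.5 follows the convention for crowding zones).
#' @param d0 foveal floor: minimum pooling diameter, degrees.
#' @param aspect radial/tangential elongation of the sectors; 0.5 gives
#'   the classic 2:1 radially elongated pooling zones.
#' @param min_weight drop regions whose total weight over the image is
#'   below this fraction of a pixel (they lie outside the field of view).
#' @return An object of class `pooling_scheme`: list with `regions`
#'   (data.frame: id, ecc_deg, angle_deg, diameter_deg, kind), `weights`
#'   (list of weight matrices), `params`, `dims`.
#' @export
build_pooling_scheme <- function(image, g = 0.5, d0 = 1.0, aspect = 0.5,
                                 min_weight = 1e-4) {
  stopifnot(inherits(image, "lum_img"))
  if (g <= 0 || d0 <= 0) stop("`g` and `d0` must be positive", call. = FALSE)
  emap <- eccentricity_map(image)
  amap <- polar_angle_map(image)
  e_max <- max(emap)
  if (e_max <= d0 / 2)
    stop(sprintf(
      "image too small: max eccentricity %.3g deg lies inside the foveal floor (d0/2 = %.3g deg)",
      e_max, d0 / 2), call. = FALSE)

  D <- radial_log_spacing(g)          # half-width = spacing in log2(e)
  u <- log2(pmax(emap, 2^-30))        # log-eccentricity (guard e = 0)
  u1 <- log2(d0 / 2) + D              # centre of the first annulus
  K <- max(1L, ceiling((log2(e_max) - u1) / D) + 1L)
  n_theta <- max(4L, round(4 * pi * aspect / g))
  dphi <- 2 * pi / n_theta

  weights <- list()
  ids <- character(0)
  tab <- list()
  add_region <- function(w, ecc, ang, diam, kind) {
    tw <- sum(w)
    if (tw < min_weight) return(invisible(NULL))
    i <- length(weights) + 1L
    weights[[i]] <<- w
    tab[[i]] <<- data.frame(id = sprintf("r%03d", i), ecc_deg = ecc,
                            angle_deg = ang, diameter_deg = diam,
                            kind = kind, stringsAsFactors = FALSE)
  }

  # Foveal disk: flat inside d0/2, fading as the first annulus rises.
  t_f <- u - u1
  w_f <- numeric(length(t_f))
  w_f[t_f <= -D] <- 1
  rise <- t_f > -D & t_f < 0
  w_f[rise] <- 1 - cos2_win(t_f[rise], D)
  dim(w_f) <- dim(emap)
  add_region(w_f, 0, 0, d0, "fovea")

  # Annular sectors.  The outermost annulus is a catch-all: its radial
  # window is clamped to cover everything beyond its centre.
  for (k in seq_len(K)) {
    uk <- u1 + (k - 1) * D
    t <- u - uk
    wr <- cos2_win(t, D)
    if (k == K) wr[t >= 0] <- 1
    dim(wr) <- dim(emap)
    ek <- 2^uk
    for (j in seq_len(n_theta)) {
      phi_j <- -pi + (j - 1) * dphi
      dphi_t <- (amap - phi_j + pi) %% (2 * pi) - pi
      wa <- cos2_win(dphi_t, dphi)
      dim(wa) <- dim(emap)
      add_region(wr * wa, ek, phi_j * 180 / pi, max(d0, g * ek), "sector")
    }
  }

  # Pixelwise renormalization: exact partition of unity even where dropped
  # out-of-field regions carried (tiny) weight.
  total <- Reduce(`+`, weights)
  if (min(total) <= 0)
    stop("internal error: pooling lattice leaves pixels uncovered", call. = FALSE)
  weights <- lapply(weights, function(w) w / total)

  structure(list(regions = do.call(rbind, tab), weights = weights,
                 params = list(g = g, d0 = d0, aspect = aspect,
                               n_theta = n_theta, log_spacing = D,
                               ppd = image$ppd, fixation = image$fixation),
                 dims = dim(emap)),
            class = "pooling_scheme")
}

#' @export
print.pooling_scheme <- function(x, ...) {
  cat(sprintf("<pooling_scheme> %d regions over %d x %d px (g=%.2g, d0=%.2g deg)\n",
              length(x$weights), x$dims[1], x$dims[2],
              x$params$g, x$params$d0))
  invisible(x)
}

#' Uniform whole-field pooling
#'
#' A degenerate scheme with a single region of uniform weight covering the
#' entire image: the classic homogeneous texture-synthesis configuration,
#' equivalent to pooling statistics over the whole patch.  Useful for
#' validating the encoder and synthesis machinery independently of the
#' foveated lattice, and for plain texture work.
#'
#' @param image a [lum_img()].
#' @return a `pooling_scheme` with one region.
#' @export
uniform_pooling_scheme <- function(image) {
  stopifnot(inherits(image, "lum_img"))
  d <- dim(image$pixels)
  structure(list(
    regions = data.frame(id = "r001", ecc_deg = 0, angle_deg = 0,
                         diameter_deg = max(d) / image$ppd, kind = "uniform",
                         stringsAsFactors = FALSE),
    weights = list(matrix(1, d[1], d[2])),
    params = list(g = NA_real_, d0 = NA_real_, aspect = NA_real_,
                  n_theta = 1L, log_spacing = NA_real_,
                  ppd = image$ppd, fixation = image$fixation),
    dims = d), class = "pooling_scheme")
}

#' Weight map of one pooling region
#'
#' @param scheme a `pooling_scheme`.
#' @param region_id region id string (`regions$id`) or integer index.
#' @return non-negative numeric matrix over image pixels.
#' @export
region_weights <- function(scheme, region_id) {
  stopifnot(inherits(scheme, "pooling_scheme"))
  i <- if (is.numeric(region_id)) as.integer(region_id)
       else match(region_id, scheme$regions$id)
  if (is.na(i) || i < 1L || i > length(scheme$weights))
    stop("unknown region id: ", region_id, call. = FALSE)
  scheme$weights[[i]]
}

#' Export pooling geometry to JSON
#'
#' Writes the region table and lattice parameters (not the pixel weight
#' maps) for inspection or plotting.
#' @param scheme a `pooling_scheme`.
#' @param path output JSON path.
#' @export
write_pooling_json <- function(scheme, path) {
  jsonlite::write_json(list(params = scheme$params,
                            regions = scheme$regions),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
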