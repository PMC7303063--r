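# Statistic-space discriminability: how far apart two stimuli are in the
# peripheral encoding, at a given fixation.  This is the model-side
# predictor of search difficulty (present-vs-absent patch separation) and
# of change visibility (per-region distance between the two members of a
# change pair).

#' Normalization ensemble for statistic-space distances
#'
#' Per-statistic scales estimated from a seeded ensemble of phase-scrambled
#' variants of a reference image: each variant keeps the reference's power
#' spectrum but randomizes its phases, is re-encoded, and the ensemble
#' standard deviation of every statistic (per region) becomes that
#' statistic's scale.  Zero-variance statistics are dropped (scale = NA)
#' and reported in the result.
#'
#' @param image reference [lum_img()].
#' @param scheme `pooling_scheme` (default parameters if omitted).
#' @param config [stat_config()].
#' @param n ensemble size.
#' @param seed RNG seed.
#' @return object of class `stat_norm`: list with `sd` (named vector of
#'   per-statistic scales, NA where degenerate), `n`, `n_dropped`.
#' @export
stat_norm_ensemble <- function(image, scheme = NULL, config = stat_config(),
                               n = 100, seed = 1) {
  stopifnot(inherits(image, "lum_img"))
  if (is.null(scheme)) scheme <- build_pooling_scheme(image)
  X <- fft2(image$pixels)
  amp <- Mod(X)
  dims <- dim(image$pixels)
  draws <- with_seed(seed, lapply(seq_len(n), function(k) {
    ph <- matrix(stats::runif(prod(dims), 0, 2 * pi), dims[1], dims[2])
    # Hermitian-symmetrize the phases so the scramble stays real
    y <- Re(stats::fft(amp * exp(1i * ph), inverse = TRUE)) / prod(dims)
    y <- pmin(pmax(y, 0), 1)
    as_stat_numeric(compute_stat_field(
      lum_img(y, image$ppd, image$fixation), scheme, config))
  }))
  M <- do.call(rbind, draws)
  sds <- apply(M, 2, stats::sd)
  dropped <- sds < 1e-12
  sds[dropped] <- NA_real_
  structure(list(sd = sds, n = n, n_dropped = sum(dropped)),
            class = "stat_norm")
}

#' Statistic-space distance between two encodings
#'
#' Z-scores every statistic by the ensemble scale and returns the Euclidean
#' distance, overall and per pooling region.  With `norm = NULL` the raw
#' (unnormalized) Euclidean distance is used; both forms satisfy the metric
#' axioms.
#'
#' @param a,b `stat_field`s computed under the same scheme and config.
#' @param norm a `stat_norm` from [stat_norm_ensemble()], a numeric vector
#'   of per-statistic scales, or NULL.
#' @return A `discriminability_report`: list with `distance`, `per_region`
#'   (named numeric), `n_stats`, `n_dropped`.
#' @export
stat_distance <- function(a, b, norm = NULL) {
  stopifnot(inherits(a, "stat_field"), inherits(b, "stat_field"))
  if (!identical(a$provenance$config, b$provenance$config) ||
      !all(a$provenance$dims == b$provenance$dims) ||
      length(a$vectors) != length(b$vectors))
    stop("stat_fields were not computed under the same configuration",
         call. = FALSE)
  va <- as_stat_numeric(a)
  vb <- as_stat_numeric(b)
  sds <- if (is.null(norm)) rep(1, length(va))
         else if (inherits(norm, "stat_norm")) norm$sd
         else as.numeric(norm)
  if (length(sds) != length(va))
    stop("normalization length does not match the statistic count",
         call. = FALSE)
  keep <- !is.na(sds) & sds > 0
  z <- (va[keep] - vb[keep]) / sds[keep]
  reg <- sub("\\..*$", "", names(va)[keep])
  per_region <- sqrt(tapply(z^2, reg, sum))
  # restore region order
  ids <- names(a$vectors)
  per_region <- per_region[ids[ids %in% names(per_region)]]
  structure(list(distance = sqrt(sum(z^2)),
                 per_region = per_region,
                 n_stats = sum(keep), n_dropped = sum(!keep)),
            class = "discriminability_report")
}

#' @export
print.discriminability_report <- function(x, ...) {
  cat(sprintf("<discriminability_report> distance %.4g over %d statistics (%d dropped)\n",
              x$distance, x$n_stats, x$n_dropped))
  invisible(x)
}

#' Search-difficulty proxy from peripheral discriminability
#'
#' Statistic-space separability of target-present from target-absent
#' crowded patches at a given eccentricity.  `n_seeds` patches of each
#' class are drawn independently (seeded flanker rotations and positional
#' jitter), encoded, and the two class means are compared in units of the
#' pooled within-class standard deviation — a linear-discriminability
#' index: the target signal must survive the natural variability of the
#' crowded patch, which is what makes conjunction-like targets hard.  A
#' larger proxy predicts easier search (a shallower reaction-time slope);
#' only orderings across conditions are interpreted.
#'
#' @param present,absent lists of arguments for [make_crowding_patch()]
#'   describing the central item when the target is present vs absent
#'   (e.g. `list(center_glyph = "T")` vs `list(center_glyph = "L")`);
#'   shared arguments (flankers, spacing) go in `...`.
#' @param ecc_deg target eccentricity, degrees.
#' @param n_seeds patches per class (>= 2).
#' @param spec base [stimulus_spec()] (ppd, item size, colors).
#' @param config [stat_config()].
#' @param seed base seed.
#' @param ridge regularizer added to every per-statistic scale, as a
#'   fraction of the mean within-class standard deviation.
#' @param ... shared [make_crowding_patch()] arguments.
#' @return list with `proxy` (separability index), `sd` (leave-one-out
#'   dispersion), `n_seeds`.
#' @export
search_difficulty_proxy <- function(present, absent, ecc_deg = 10,
                                    n_seeds = 10,
                                    spec = stimulus_spec("crowding_triplet"),
                                    config = stat_config(), seed = 1,
                                    ridge = 0.05, ...) {
  if (n_seeds < 2) stop("need at least two seeds", call. = FALSE)
  scheme <- NULL
  encode <- function(args, sd) {
    sp <- spec; sp$seed <- sd
    img <- do.call(make_crowding_patch,
                   c(list(spec = sp, ecc_deg = ecc_deg), args, list(...)))$image
    if (is.null(scheme)) scheme <<- build_pooling_scheme(img)
    as_stat_numeric(compute_stat_field(img, scheme, config))
  }
  e1 <- encode(present, seed + 1)
  P <- rbind(e1, t(vapply(seq_len(n_seeds - 1) + 1,
                          function(k) encode(present, seed + k), e1)))
  A <- t(vapply(seq_len(n_seeds),
                function(k) encode(absent, seed + 1000 + k), e1))
  sep <- function(P, A) {
    s <- sqrt((apply(P, 2, stats::var) + apply(A, 2, stats::var)) / 2)
    s <- s + ridge * mean(s)
    if (all(s == 0)) return(0)
    z2 <- ((colMeans(P) - colMeans(A)) / s)^2
    # debias: under no signal each squared z is ~ 2/n by sampling alone
    sqrt(max(0, sum(z2 - 2 / nrow(P))))
  }
  proxy <- sep(P, A)
  loo <- vapply(seq_len(n_seeds), function(k)
    sep(P[-k, , drop = FALSE], A[-k, , drop = FALSE]), numeric(1))
  list(proxy = proxy, sd = stats::sd(loo), n_seeds = n_seeds)
}

#' Change visibility map for an image pair
#'
#' Per-region discriminability between two images (e.g. the two members of
#' a change pair) at a common fixation.  Each region is scored by its most
#' diagnostic single statistic — the largest absolute difference measured
#' on the statistic's natural scale (correlations on \[-1,1\], marginals
#' relative to the luminance range) — and the overall score is the best
#' region.  Near fixation the pooling regions are small, so a changed item
#' dominates some region's statistics and the score is high; far from
#' fixation the change is pooled together with surrounding clutter and the
#' score falls.
#'
#' @param a,b [lum_img()]s with identical dimensions (fixation taken from
#'   `a` unless `fixation` is given).
#' @param fixation optional fixation override (row, col) px.
#' @param config [stat_config()].
#' @param norm optional per-statistic scales replacing the natural scales
#'   (a `stat_norm` or numeric vector as in [stat_distance()]).
#' @return list with `per_region` (data.frame: id, ecc_deg, angle_deg,
#'   diameter_deg, distance), `score`, `scheme`.
#' @export
change_visibility <- function(a, b, fixation = NULL, config = stat_config(),
                              norm = NULL) {
  stopifnot(inherits(a, "lum_img"), inherits(b, "lum_img"))
  if (!all(dim(a$pixels) == dim(b$pixels)))
    stop("images must share geometry", call. = FALSE)
  if (!is.null(fixation)) {
    a <- lum_img(a$pixels, a$ppd, fixation)
    b <- lum_img(b$pixels, b$ppd, fixation)
  } else {
    b <- lum_img(b$pixels, b$ppd, a$fixation)
  }
  scheme <- build_pooling_scheme(a)
  fa <- compute_stat_field(a, scheme, config)
  fb <- compute_stat_field(b, scheme, config)
  ext_sd <- if (is.null(norm)) NULL
            else if (inherits(norm, "stat_norm")) norm$sd else as.numeric(norm)
  nstat <- stat_count(config)
  per <- vapply(seq_along(fa$vectors), function(r) {
    va <- fa$vectors[[r]]; vb <- fb$vectors[[r]]
    d <- abs(as_stat_numeric(va) - as_stat_numeric(vb))
    sc <- if (is.null(ext_sd)) unlist(stat_entry_scales(va))
          else ext_sd[(r - 1) * nstat + seq_len(nstat)]
    keep <- !is.na(sc) & sc > 0
    if (!any(keep)) return(0)
    max(d[keep] / sc[keep])
  }, numeric(1))
  tab <- scheme$regions
  tab$distance <- per
  list(per_region = tab, score = max(per), scheme = scheme)
}
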