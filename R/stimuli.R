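# Seeded synthetic-stimulus generator: letter arrays, search displays,
# crowding patches, colored-square arrays and change pairs.  Everything is
# rendered from a built-in stroke-segment font and analytic shapes, so the
# same spec and seed give bit-identical stimuli on any platform.  All
# geometry is specified in degrees and converted through the ppd scale;
# the returned ground truth is sufficient to re-render the stimulus.

# Stroke-segment font: each glyph is a list of segments (x1, y1, x2, y2)
# in a unit box, x rightward, y upward.
STROKE_FONT <- list(
  A = rbind(c(0, 0, .5, 1), c(.5, 1, 1, 0), c(.2, .4, .8, .4)),
  E = rbind(c(0, 0, 0, 1), c(0, 1, 1, 1), c(0, .5, .7, .5), c(0, 0, 1, 0)),
  F = rbind(c(0, 0, 0, 1), c(0, 1, 1, 1), c(0, .5, .7, .5)),
  H = rbind(c(0, 0, 0, 1), c(1, 0, 1, 1), c(0, .5, 1, .5)),
  I = rbind(c(.5, 0, .5, 1)),
  K = rbind(c(0, 0, 0, 1), c(0, .5, 1, 1), c(0, .5, 1, 0)),
  L = rbind(c(0, 0, 0, 1), c(0, 0, 1, 0)),
  M = rbind(c(0, 0, 0, 1), c(0, 1, .5, .5), c(.5, .5, 1, 1), c(1, 1, 1, 0)),
  N = rbind(c(0, 0, 0, 1), c(0, 1, 1, 0), c(1, 0, 1, 1)),
  T = rbind(c(0, 1, 1, 1), c(.5, 0, .5, 1)),
  U = rbind(c(0, 1, 0, 0), c(0, 0, 1, 0), c(1, 0, 1, 1)),
  V = rbind(c(0, 1, .5, 0), c(.5, 0, 1, 1)),
  W = rbind(c(0, 1, .25, 0), c(.25, 0, .5, .6), c(.5, .6, .75, 0), c(.75, 0, 1, 1)),
  X = rbind(c(0, 0, 1, 1), c(0, 1, 1, 0)),
  Y = rbind(c(0, 1, .5, .5), c(1, 1, .5, .5), c(.5, .5, .5, 0)),
  Z = rbind(c(0, 1, 1, 1), c(1, 1, 0, 0), c(0, 0, 1, 0)),
  bar = rbind(c(.5, .04, .5, .96))
)

#' Names of the available stroke-font glyphs
#' @return character vector of letters.
#' @export
font_letters <- function() setdiff(names(STROKE_FONT), "bar")

#' Stimulus specification
#'
#' Common geometry and content parameters for every display class.  The
#' same spec and seed always produce a bit-identical stimulus.
#'
#' @param kind one of `"letter_array"`, `"crowding_triplet"`,
#'   `"search_array"`, `"vwm_array"`, `"change_pair"`.
#' @param ppd pixels per degree.
#' @param item_deg item size (letter height / bar length / square side), deg.
#' @param spacing_deg center-to-center item spacing (grid pitch), deg.
#' @param grid `(rows, cols)` for letter arrays and for the placement grid
#'   of search and square arrays.
#' @param n_items item count for search / square arrays.
#' @param letters letter set to sample from.
#' @param palette list/matrix of RGB triples for colored squares; default 9
#'   maximally spaced hues.
#' @param margin_deg empty margin around the item grid, deg.
#' @param fixation optional `(row, col)` fixation in px (default: centre).
#' @param bg background luminance.
#' @param background `"gray"` (uniform) or `"texture"` (granular gray
#'   clutter) behind colored-square arrays.
#' @param ink stroke luminance for letters/bars.
#' @param stroke_deg stroke width, deg.
#' @param seed RNG seed for content and jitter.
#' @return list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("letter_array", "crowding_triplet",
                                   "search_array", "vwm_array", "change_pair"),
                          ppd = 16, item_deg = 1, spacing_deg = 1.5,
                          grid = c(3, 4), n_items = 8, letters = font_letters(),
                          palette = NULL, margin_deg = 1, fixation = NULL,
                          bg = 0.85, ink = 0.1, stroke_deg = 0.12,
                          background = "gray", seed = 1) {
  kind <- match.arg(kind)
  if (is.null(palette)) palette <- default_palette()
  structure(list(kind = kind, ppd = ppd, item_deg = item_deg,
                 spacing_deg = spacing_deg, grid = as.integer(grid),
                 n_items = as.integer(n_items), letters = letters,
                 palette = palette, margin_deg = margin_deg,
                 fixation = fixation, bg = bg, ink = ink,
                 stroke_deg = stroke_deg, background = background,
                 seed = seed),
            class = "stimulus_spec")
}

#' Default palette: 9 maximally spaced hues
#' @return 9 x 3 matrix of RGB values in \[0,1\].
#' @export
default_palette <- function() {
  t(sapply((0:8) / 9, function(h) grDevices::col2rgb(grDevices::hsv(h, 1, 1)) / 255))
}

# Rotate glyph segments by `angle` degrees about the box centre.
rotate_segments <- function(segs, angle) {
  if (angle == 0) return(segs)
  a <- angle * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  rot <- function(x, y) {
    p <- R %*% rbind(x - 0.5, y - 0.5)
    rbind(p[1, ] + 0.5, p[2, ] + 0.5)
  }
  p1 <- rot(segs[, 1], segs[, 2]); p2 <- rot(segs[, 3], segs[, 4])
  cbind(p1[1, ], p1[2, ], p2[1, ], p2[2, ])
}

# Composite a glyph onto the canvas.  Centre in px (row, col, 0-based),
# size and stroke in px.  Antialiased with a 1-px linear coverage ramp.
draw_glyph <- function(canvas, glyph, center_px, size_px, stroke_px, ink,
                       angle = 0) {
  segs <- STROKE_FONT[[glyph]]
  if (is.null(segs)) stop("no glyph for '", glyph, "'", call. = FALSE)
  segs <- rotate_segments(segs, angle)
  # unit-box -> image px (rows grow downward)
  r1 <- center_px[1] + (0.5 - segs[, 2]) * size_px
  c1 <- center_px[2] + (segs[, 1] - 0.5) * size_px
  r2 <- center_px[1] + (0.5 - segs[, 4]) * size_px
  c2 <- center_px[2] + (segs[, 3] - 0.5) * size_px
  pad <- stroke_px / 2 + 1.5
  rr <- max(1L, floor(min(r1, r2) - pad) + 1L):min(nrow(canvas), ceiling(max(r1, r2) + pad) + 1L)
  cc <- max(1L, floor(min(c1, c2) - pad) + 1L):min(ncol(canvas), ceiling(max(c1, c2) + pad) + 1L)
  if (!length(rr) || !length(cc)) return(canvas)
  P_r <- outer(rr - 1, rep(1, length(cc)))
  P_c <- outer(rep(1, length(rr)), cc - 1)
  d <- matrix(Inf, length(rr), length(cc))
  for (i in seq_len(nrow(segs))) {
    vr <- r2[i] - r1[i]; vc <- c2[i] - c1[i]
    L2 <- vr^2 + vc^2
    if (L2 < 1e-12) {
      di <- sqrt((P_r - r1[i])^2 + (P_c - c1[i])^2)
    } else {
      t <- pmin(1, pmax(0, ((P_r - r1[i]) * vr + (P_c - c1[i]) * vc) / L2))
      di <- sqrt((P_r - (r1[i] + t * vr))^2 + (P_c - (c1[i] + t * vc))^2)
    }
    d <- pmin(d, di)
  }
  cov <- pmin(1, pmax(0, stroke_px / 2 + 0.5 - d))
  canvas[rr, cc] <- canvas[rr, cc] * (1 - cov) + ink * cov
  canvas
}

# Filled axis-aligned square, antialiased, color = scalar luminance or
# length-3 RGB (canvas then must be a 3-plane array).
draw_square <- function(canvas, center_px, side_px, color) {
  half <- side_px / 2
  rr <- max(1L, floor(center_px[1] - half - 1) + 1L):min(dim(canvas)[1], ceiling(center_px[1] + half + 1) + 1L)
  cc <- max(1L, floor(center_px[2] - half - 1) + 1L):min(dim(canvas)[2], ceiling(center_px[2] + half + 1) + 1L)
  covr <- pmin(1, pmax(0, half + 0.5 - abs((rr - 1) - center_px[1])))
  covc <- pmin(1, pmax(0, half + 0.5 - abs((cc - 1) - center_px[2])))
  cov <- outer(covr, covc)
  if (length(color) == 1L) {
    canvas[rr, cc] <- canvas[rr, cc] * (1 - cov) + color * cov
  } else {
    for (k in 1:3)
      canvas[rr, cc, k] <- canvas[rr, cc, k] * (1 - cov) + color[k] * cov
  }
  canvas
}

# Canvas size for a grid spec: grid extent plus margins.
spec_canvas_dims <- function(spec) {
  h <- ceiling((spec$grid[1] * spec$spacing_deg + 2 * spec$margin_deg) * spec$ppd)
  w <- ceiling((spec$grid[2] * spec$spacing_deg + 2 * spec$margin_deg) * spec$ppd)
  c(h, w)
}

spec_cell_centers <- function(spec, dims) {
  # centres of the (rows x cols) grid cells, px, 0-based, grid centred
  rows <- spec$grid[1]; cols <- spec$grid[2]
  pitch <- spec$spacing_deg * spec$ppd
  r0 <- (dims[1] - 1) / 2 - (rows - 1) / 2 * pitch
  c0 <- (dims[2] - 1) / 2 - (cols - 1) / 2 * pitch
  list(rows = r0 + (seq_len(rows) - 1) * pitch,
       cols = c0 + (seq_len(cols) - 1) * pitch)
}

spec_fixation <- function(spec, dims) {
  if (!is.null(spec$fixation)) spec$fixation else (dims - 1) / 2
}

#' Letter array stimulus
#'
#' Dark letters on a light background in a regular grid (a Sperling-style
#' partial-report array).  Letters are sampled from the spec's letter set
#' under the spec's seed.
#'
#' @param spec a [stimulus_spec()]; `grid`, `item_deg`, `spacing_deg` and
#'   `letters` control the display.
#' @return list with `image` (a [lum_img()]) and `ground_truth`
#'   (data.frame: grid_row, grid_col, letter, center_row, center_col in px).
#' @export
make_letter_array <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (length(spec$letters) == 0L || any(spec$grid < 1L))
    stop("letter set and grid must be non-empty", call. = FALSE)
  if (spec$item_deg > spec$spacing_deg)
    stop("letters larger than the grid pitch would overlap", call. = FALSE)
  dims <- spec_canvas_dims(spec)
  cen <- spec_cell_centers(spec, dims)
  gt <- expand.grid(grid_row = seq_len(spec$grid[1]),
                    grid_col = seq_len(spec$grid[2]))
  gt$letter <- with_seed(spec$seed,
    sample(spec$letters, nrow(gt), replace = TRUE))
  gt$center_row <- cen$rows[gt$grid_row]
  gt$center_col <- cen$cols[gt$grid_col]
  canvas <- matrix(spec$bg, dims[1], dims[2])
  for (i in seq_len(nrow(gt)))
    canvas <- draw_glyph(canvas, gt$letter[i],
                         c(gt$center_row[i], gt$center_col[i]),
                         spec$item_deg * spec$ppd,
                         spec$stroke_deg * spec$ppd, spec$ink)
  list(image = lum_img(canvas, spec$ppd, spec_fixation(spec, dims)),
       ground_truth = gt)
}

# Jittered non-overlapping placement: pick n distinct grid cells, jitter
# each item uniformly inside its cell keeping the item box inside.
place_items <- function(spec, n) {
  dims <- spec_canvas_dims(spec)
  cen <- spec_cell_centers(spec, dims)
  n_cells <- spec$grid[1] * spec$grid[2]
  if (n > n_cells)
    stop(sprintf("%d items do not fit on a %dx%d grid", n,
                 spec$grid[1], spec$grid[2]), call. = FALSE)
  jmax <- max(0, (spec$spacing_deg - spec$item_deg) / 2 * spec$ppd - 1)
  cells <- sample(n_cells, n)
  gr <- (cells - 1L) %% spec$grid[1] + 1L
  gc <- (cells - 1L) %/% spec$grid[1] + 1L
  data.frame(center_row = cen$rows[gr] + stats::runif(n, -jmax, jmax),
             center_col = cen$cols[gc] + stats::runif(n, -jmax, jmax))
}

#' Visual search display
#'
#' Items placed with seeded positional jitter on a grid; exactly one target
#' iff `target_present`.
#'
#' Conditions: `feature_popout` — vertical bar distractors, 45-deg tilted
#' bar target; `t_among_l` — rotated L distractors, rotated T target (same
#' strokes, different arrangement); `conjunction` — dark tilted target
#' among dark vertical and light tilted distractors.
#'
#' @param spec a [stimulus_spec()] (`n_items`, `grid`, `item_deg` used).
#' @param condition search condition (see above).
#' @param target_present logical.
#' @return list with `image` ([lum_img()]) and `ground_truth` (data.frame:
#'   center_row, center_col, glyph, angle, ink, is_target).
#' @export
make_search_array <- function(spec,
                              condition = c("feature_popout", "t_among_l",
                                            "conjunction"),
                              target_present = TRUE) {
  stopifnot(inherits(spec, "stimulus_spec"))
  condition <- match.arg(condition)
  n <- spec$n_items
  if (n < 1L) stop("need at least one item", call. = FALSE)
  gt <- with_seed(spec$seed, {
    pos <- place_items(spec, n)
    is_target <- rep(FALSE, n)
    if (target_present) is_target[sample(n, 1L)] <- TRUE
    g <- switch(condition,
      feature_popout = data.frame(glyph = "bar",
                                  angle = ifelse(is_target, 45, 0),
                                  ink = spec$ink),
      t_among_l = data.frame(glyph = ifelse(is_target, "T", "L"),
                             angle = sample(c(0, 90, 180, 270), n, TRUE),
                             ink = spec$ink),
      conjunction = {
        tilted <- stats::runif(n) < 0.5
        light <- ifelse(tilted, (spec$bg + spec$ink) / 2, spec$ink)
        data.frame(glyph = "bar",
                   angle = ifelse(is_target | tilted, 45, 0),
                   ink = ifelse(is_target, spec$ink, light))
      })
    cbind(pos, g, is_target = is_target)
  })
  dims <- spec_canvas_dims(spec)
  canvas <- matrix(spec$bg, dims[1], dims[2])
  for (i in seq_len(nrow(gt)))
    canvas <- draw_glyph(canvas, gt$glyph[i],
                         c(gt$center_row[i], gt$center_col[i]),
                         spec$item_deg * spec$ppd,
                         spec$stroke_deg * spec$ppd, gt$ink[i],
                         angle = gt$angle[i])
  list(image = lum_img(canvas, spec$ppd, spec_fixation(spec, dims)),
       ground_truth = gt)
}

#' Colored-square array (visual working memory display)
#'
#' `n_items` colored squares at jittered grid positions on a uniform gray
#' background — the classic change-detection display.
#'
#' @param n_items number of squares (0 gives a uniform gray field).
#' @param palette matrix of RGB rows to sample colors from.
#' @param spec a [stimulus_spec()].
#' @return list with `raster` (H x W x 3 array), `image` (luminance
#'   [lum_img()]), and `ground_truth` (center_row, center_col, color_index).
#' @export
make_vwm_array <- function(n_items = 8, palette = NULL, spec = stimulus_spec("vwm_array")) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (is.null(palette)) palette <- spec$palette
  palette <- as.matrix(palette)
  if (nrow(palette) == 0L) stop("palette must be non-empty", call. = FALSE)
  gt <- if (n_items > 0) {
    with_seed(spec$seed, {
      pos <- place_items(spec, n_items)
      pos$color_index <- sample(nrow(palette), n_items, replace = TRUE)
      pos
    })
  } else data.frame(center_row = numeric(0), center_col = numeric(0),
                    color_index = integer(0))
  render_vwm(gt, palette, spec)
}

render_vwm <- function(gt, palette, spec) {
  dims <- spec_canvas_dims(spec)
  canvas <- array(0.5, c(dims[1], dims[2], 3))
  if (identical(spec$background, "texture")) {
    # cluttered backdrop: a granular gray texture (seeded independently of
    # the item layout so change pairs share it exactly)
    bg <- make_noise_texture(dims[2], dims[1], ppd = spec$ppd,
                             grain_deg = 0.2, kind = "gaussian",
                             seed = spec$seed + 131071)$pixels
    for (k in 1:3) canvas[, , k] <- bg
  }
  for (i in seq_len(nrow(gt)))
    canvas <- draw_square(canvas, c(gt$center_row[i], gt$center_col[i]),
                          spec$item_deg * spec$ppd, palette[gt$color_index[i], ])
  fix <- spec_fixation(spec, dims)
  list(raster = canvas,
       image = to_luminance(canvas, ppd = spec$ppd, fixation = fix),
       ground_truth = gt)
}

#' Change pair: two displays differing in a single item
#'
#' Renders a base colored-square array and a copy in which one item's color
#' is replaced; all other pixels are identical.
#'
#' @param spec a [stimulus_spec()] for the base array.
#' @param item index of the item to change.
#' @param new_color_index palette row of the replacement color (must differ
#'   from the item's color).
#' @param n_items squares in the base array.
#' @param palette RGB palette matrix.
#' @return list with `a`, `b` (as [make_vwm_array()] results) and `record`
#'   (item index, position, old/new color).
#' @export
make_change_pair <- function(spec, item = 1L, new_color_index = NULL,
                             n_items = 8, palette = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (is.null(palette)) palette <- spec$palette
  palette <- as.matrix(palette)
  a <- make_vwm_array(n_items, palette, spec)
  gt <- a$ground_truth
  if (item < 1L || item > nrow(gt)) stop("invalid item index", call. = FALSE)
  old <- gt$color_index[item]
  if (is.null(new_color_index))
    new_color_index <- with_seed(spec$seed + 1L,
      sample(setdiff(seq_len(nrow(palette)), old), 1L))
  if (new_color_index == old)
    stop("new color equals the old color: not a change", call. = FALSE)
  gt$color_index[item] <- new_color_index
  b <- render_vwm(gt, palette, spec)
  list(a = a, b = b,
       record = list(item = item,
                     center_row = gt$center_row[item],
                     center_col = gt$center_col[item],
                     old_color = old, new_color = new_color_index))
}

#' Seeded noise texture
#'
#' Binary (thresholded) or Gaussian noise with a controllable grain size:
#' white noise is lowpass-filtered to the requested grain and, for the
#' binary kind, thresholded at its median so half the field is dark and
#' half light.  Grain is specified in degrees and converted through ppd,
#' so the same spec at two ppd values yields similar-looking textures.
#'
#' @param width,height size in px.
#' @param ppd pixels per degree.
#' @param grain_deg texture grain (approximate element size), degrees.
#' @param kind `"binary"` (two-level) or `"gaussian"`.
#' @param levels the two luminances of a binary texture.
#' @param fixation optional fixation (row, col) px.
#' @param seed RNG seed.
#' @return a [lum_img()].
#' @export
make_noise_texture <- function(width = 128, height = 128, ppd = 16,
                               grain_deg = 0.25, kind = c("binary", "gaussian"),
                               levels = c(0.15, 0.85), fixation = NULL,
                               seed = 1) {
  kind <- match.arg(kind)
  z <- with_seed(seed, matrix(stats::rnorm(width * height), height, width))
  grain_px <- max(1, grain_deg * ppd)
  if (grain_px > 1) {
    wy <- fft_freqs(height); wx <- fft_freqs(width)
    r <- sqrt(outer(wy^2, wx^2, `+`))
    G <- exp(-(r * grain_px / 2)^2)
    z <- ifft2(fft2(z) * G)
  }
  if (kind == "binary") {
    px <- ifelse(z > stats::median(z), levels[2], levels[1])
  } else {
    z <- (z - mean(z)) / stats::sd(as.vector(z))
    px <- pmin(pmax(0.5 + 0.15 * z, 0), 1)
  }
  if (is.null(fixation)) fixation <- (c(height, width) - 1) / 2
  lum_img(px, ppd = ppd, fixation = fixation)
}

#' Crowded peripheral patch
#'
#' A central item at a given eccentricity (rightward of fixation) flanked
#' by distractor items — the target-present / target-absent patches whose
#' statistic-space separation predicts search difficulty.  The fixation is
#' placed on the left edge at the item's height.
#'
#' @param spec a [stimulus_spec()] (ppd, item size, colors, seed).
#' @param center_glyph,center_angle glyph name and rotation of the central
#'   item (the target when present, a distractor otherwise).
#' @param flanker_glyph flanker glyph name.
#' @param flanker_angles rotation set the flankers sample from.
#' @param ecc_deg target eccentricity, degrees.
#' @param flanker_spacing_deg centre-to-centre target-flanker distance.
#' @param n_flankers number of flankers (2 = horizontal triplet; more are
#'   placed on a ring).
#' @param jitter_deg seeded uniform positional jitter applied to every
#'   item, degrees (half-range).
#' @param field_deg `(height, width)` of the canvas in degrees.
#' @return list with `image` ([lum_img()], fixation at the left edge) and
#'   `ground_truth`.
#' @export
make_crowding_patch <- function(spec, center_glyph = "T", center_angle = 0,
                                flanker_glyph = "L",
                                flanker_angles = c(0, 90, 180, 270),
                                ecc_deg = 10, flanker_spacing_deg = 2,
                                n_flankers = 2, jitter_deg = 0.15,
                                field_deg = c(ecc_deg * 0.8, ecc_deg * 1.5)) {
  stopifnot(inherits(spec, "stimulus_spec"))
  dims <- ceiling(field_deg * spec$ppd)
  fix <- c((dims[1] - 1) / 2, 1)
  tr <- fix[1]; tc <- fix[2] + ecc_deg * spec$ppd
  if (tc > dims[2] - spec$item_deg * spec$ppd)
    stop("patch exceeds the field of view", call. = FALSE)
  ang <- if (n_flankers == 2) c(pi, 0) else (seq_len(n_flankers) - 1) * 2 * pi / n_flankers
  gt <- with_seed(spec$seed, {
    n <- n_flankers + 1L
    jit <- matrix(stats::runif(2 * n, -jitter_deg, jitter_deg) * spec$ppd,
                  n, 2)
    data.frame(
      glyph = c(center_glyph, rep(flanker_glyph, n_flankers)),
      angle = c(center_angle, sample(flanker_angles, n_flankers, TRUE)),
      center_row = c(tr, tr + sin(ang) * flanker_spacing_deg * spec$ppd) + jit[, 1],
      center_col = c(tc, tc + cos(ang) * flanker_spacing_deg * spec$ppd) + jit[, 2],
      is_target = c(TRUE, rep(FALSE, n_flankers)))
  })
  canvas <- matrix(spec$bg, dims[1], dims[2])
  for (i in seq_len(nrow(gt)))
    canvas <- draw_glyph(canvas, gt$glyph[i],
                         c(gt$center_row[i], gt$center_col[i]),
                         spec$item_deg * spec$ppd,
                         spec$stroke_deg * spec$ppd, spec$ink,
                         angle = gt$angle[i])
  list(image = lum_img(canvas, spec$ppd, fix), ground_truth = gt)
}
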