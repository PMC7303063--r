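make_small_field <- function(seed, fixation = NULL) {
  img <- make_noise_texture(48, 48, ppd = 8, grain_deg = 0.3, seed = seed,
                            fixation = fixation)
  scheme <- build_pooling_scheme(img)
  list(field = compute_stat_field(img, scheme, stat_config(S = 2, O = 3, M = 3)),
       img = img, scheme = scheme)
}

test_that("the z-scored distance satisfies the metric axioms", {
  a <- make_small_field(1)
  b <- make_small_field(2, fixation = a$img$fixation)
  c <- make_small_field(3, fixation = a$img$fixation)
  n <- length(as_stat_numeric(a$field))
  sds <- with_seed(5, runif(n, 0.5, 2))
  dab <- stat_distance(a$field, b$field, sds)$distance
  dba <- stat_distance(b$field, a$field, sds)$distance
  dac <- stat_distance(a$field, c$field, sds)$distance
  dcb <- stat_distance(c$field, b$field, sds)$distance
  expect_equal(stat_distance(a$field, a$field, sds)$distance, 0)
  expect_equal(dab, dba)
  expect_lte(dab, dac + dcb + 1e-12)
})

test_that("the distance matches a hand-rolled z-score computation", {
  a <- make_small_field(4)
  b <- make_small_field(6, fixation = a$img$fixation)
  va <- as_stat_numeric(a$field); vb <- as_stat_numeric(b$field)
  sds <- with_seed(7, runif(length(va), 0.1, 3))
  expect_equal(stat_distance(a$field, b$field, sds)$distance,
               sqrt(sum(((va - vb) / sds)^2)), tolerance = 1e-12)
})

test_that("mismatched configurations are rejected", {
  a <- make_small_field(1)
  img <- make_noise_texture(48, 48, ppd = 8, seed = 2, fixation = a$img$fixation)
  f2 <- compute_stat_field(img, a$scheme, stat_config(S = 2, O = 3, M = 5))
  expect_error(stat_distance(a$field, f2), "configuration")
  expect_error(stat_distance(a$field, make_small_field(2)$field,
                             norm = c(1, 2, 3)), "length")
})

test_that("phase-scrambled ensembles give usable normalizations", {
  a <- make_small_field(9)
  nrm <- stat_norm_ensemble(a$img, a$scheme, stat_config(S = 2, O = 3, M = 3),
                            n = 12, seed = 3)
  expect_equal(length(nrm$sd), length(as_stat_numeric(a$field)))
  expect_true(all(nrm$sd[!is.na(nrm$sd)] > 0))
  b <- make_small_field(10, fixation = a$img$fixation)
  expect_gt(stat_distance(a$field, b$field, nrm)$distance, 0)
})

test_that("a degenerate present/absent pair yields a zero proxy", {
  sp <- stimulus_spec("crowding_triplet", ppd = 6, seed = 1)
  same <- list(center_glyph = "L", center_angle = 0)
  res <- search_difficulty_proxy(same, same, ecc_deg = 6, n_seeds = 4,
                                 spec = sp, config = stat_config(S = 2, O = 3, M = 3),
                                 field_deg = c(5, 9))
  expect_equal(res$proxy, 0, tolerance = 1e-10)
})

test_that("closer flankers crowd the target and shrink discriminability", {
  sp <- stimulus_spec("crowding_triplet", ppd = 8, item_deg = 1, seed = 1)
  proxy_at <- function(spacing)
    search_difficulty_proxy(
      present = list(center_glyph = "bar", center_angle = 45),
      absent  = list(center_glyph = "bar", center_angle = 0),
      ecc_deg = 10, n_seeds = 8, spec = sp,
      flanker_glyph = "bar", flanker_angles = 0,
      flanker_spacing_deg = spacing, field_deg = c(8, 14), seed = 1)$proxy
  expect_gt(proxy_at(2), proxy_at(0.7))
})

test_that("identical images have an all-zero change map", {
  img <- make_noise_texture(48, 48, ppd = 8, seed = 2)
  cv <- change_visibility(img, img, config = stat_config(S = 2, O = 3, M = 3))
  expect_equal(cv$score, 0, tolerance = 1e-12)
})

test_that("a one-item change registers only near the changed item", {
  sp <- stimulus_spec("vwm_array", ppd = 8, item_deg = 1, spacing_deg = 2,
                      grid = c(3, 3), margin_deg = 0.75, seed = 5)
  cp <- make_change_pair(sp, item = 2, n_items = 6)
  fix <- c(0, 0)   # fixate a corner so regions vary in size
  cv <- change_visibility(cp$a$image, cp$b$image, fixation = fix,
                          config = stat_config(S = 2, O = 3, M = 3))
  tab <- cv$per_region
  expect_gt(cv$score, 0)
  # the most diagnostic region overlaps the changed square (the spectral
  # filters ring faintly everywhere, so locality is strongest, not strict)
  ch <- c(cp$record$center_row, cp$record$center_col)
  half <- sp$item_deg * sp$ppd / 2 + 4
  best <- tab$id[which.max(tab$distance)]
  w <- region_weights(cv$scheme, best)
  rr <- max(1, floor(ch[1] - half)):min(nrow(w), ceiling(ch[1] + half))
  cc <- max(1, floor(ch[2] - half)):min(ncol(w), ceiling(ch[2] + half))
  expect_gt(max(w[rr, cc]), 0.05)
})
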