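test_that("the statistic count follows its closed form", {
  # minimal configuration: marginals + residual variances + one band's
  # energy pair only (no offsets, no pairs, no scale pairs)
  expect_equal(stat_count(stat_config(S = 1, O = 1, M = 1)), 10L)
  expect_equal(stat_count(stat_config(S = 2, O = 2, M = 3)),
               7L + 2L + 8L + (2 + 1 + 4) * 4L + 2L + 2L * 4L)
  counts <- vapply(c(3, 5, 7, 9), function(M) stat_count(stat_config(M = M)),
                   integer(1))
  expect_true(all(diff(counts) > 0))
  # default configuration stays within the model's nominal budget
  expect_lte(stat_count(stat_config()), 1000L)
})

test_that("a statistic vector has exactly stat_count entries", {
  set.seed(5)
  img <- lum_img(matrix(runif(64 * 64), 64, 64), ppd = 8)
  cfg <- stat_config(S = 3)
  pyr <- build_pyramid(img, S = 3, O = 4)
  v <- compute_region_stats(pyr, oracle_weight_map(64, 64), cfg)
  expect_length(unlist(unclass(v)), stat_count(cfg))
  expect_length(as_stat_numeric(v), stat_count(cfg))
})

test_that("constant regions trigger the degenerate-variance rule", {
  img <- lum_img(matrix(0.42, 64, 64), ppd = 8)
  cfg <- stat_config(S = 3)
  v <- compute_region_stats(build_pyramid(img, 3, 4),
                            oracle_weight_map(64, 64), cfg)
  expect_equal(unname(v$marginal["var"]), 0, tolerance = 1e-12)
  expect_equal(unname(v$marginal["mean"]), 0.42, tolerance = 1e-12)
  expect_true(all(c(v$autocorr, v$mag_acorr, v$mag_ocorr,
                    v$mag_scorr, v$phase_scorr) == 0))
})

test_that("weighted moments and correlations match the naive oracle", {
  set.seed(31)
  x <- matrix(runif(16 * 16), 16, 16)
  img <- lum_img(x, ppd = 4)
  cfg <- stat_config(S = 2, O = 3, M = 3)
  pyr <- build_pyramid(img, S = 2, O = 3)
  w <- oracle_weight_map(16, 16)
  v <- compute_region_stats(pyr, w, cfg)

  mom <- oracle_wmoments(x, w)
  expect_equal(unname(v$marginal[c("mean", "var", "skew", "kurt")]),
               unname(mom), tolerance = 1e-10)

  offs <- rbind(c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  ac <- vapply(seq_len(nrow(offs)), function(k)
    oracle_wautocorr(x, w, offs[k, 1], offs[k, 2]), numeric(1))
  expect_equal(unname(v$autocorr[1:4]), ac, tolerance = 1e-10)
})

test_that("a field is order-independent and deterministic", {
  set.seed(8)
  img <- lum_img(matrix(runif(64 * 64), 64, 64), ppd = 8)
  sch <- build_pooling_scheme(img)
  cfg <- stat_config(S = 3)
  f1 <- compute_stat_field(img, sch, cfg)
  f2 <- compute_stat_field(img, sch, cfg)
  expect_identical(as_stat_numeric(f1), as_stat_numeric(f2))
  # region ids bijective with the scheme
  expect_identical(names(f1$vectors), sch$regions$id)
})

test_that("uniform pooling statistics are invariant to circular shifts", {
  set.seed(12)
  img <- lum_img(matrix(runif(64 * 64), 64, 64), ppd = 8)
  sh <- img$pixels[c(17:64, 1:16), c(33:64, 1:32)]
  cfg <- stat_config(S = 3)
  f1 <- compute_stat_field(img, uniform_pooling_scheme(img), cfg)
  img2 <- lum_img(sh, ppd = 8)
  f2 <- compute_stat_field(img2, uniform_pooling_scheme(img2), cfg)
  a <- as_stat_numeric(f1); b <- as_stat_numeric(f2)
  expect_equal(a, b, tolerance = 0.02)
})

test_that("the encoding keeps texture identity while abstracting layout", {
  # two draws of the same noise process sit closer together in statistic
  # space than either sits to a letter array: texture-level information is
  # retained while precise pixel arrangement is discarded
  cfg <- stat_config(S = 3)
  mk <- function(seed) make_noise_texture(64, 64, ppd = 8, seed = seed)
  n1 <- mk(1); n2 <- mk(2)
  sp <- stimulus_spec("letter_array", ppd = 8, item_deg = 1,
                      spacing_deg = 1.6, grid = c(4, 4), margin_deg = 0.9,
                      seed = 3)
  la <- make_letter_array(sp)$image
  la_px <- la$pixels[1:64, 1:64]
  la64 <- lum_img(la_px, ppd = 8)
  sch <- build_pooling_scheme(n1)
  f1 <- compute_stat_field(n1, sch, cfg)
  f2 <- compute_stat_field(lum_img(n2$pixels, 8, n1$fixation), sch, cfg)
  fl <- compute_stat_field(lum_img(la64$pixels, 8, n1$fixation), sch, cfg)
  nrm <- stat_norm_ensemble(n1, sch, cfg, n = 20, seed = 99)
  d_noise <- stat_distance(f1, f2, nrm)$distance
  d_letters <- stat_distance(f1, fl, nrm)$distance
  expect_lt(d_noise, d_letters)
})

test_that("geometry mismatches are rejected", {
  img <- lum_img(matrix(runif(64 * 64), 64, 64), ppd = 8)
  other <- lum_img(matrix(0.5, 32, 32), ppd = 8)
  sch <- build_pooling_scheme(other)
  expect_error(compute_stat_field(img, sch), "geometry")
  pyr <- build_pyramid(img, 3, 4)
  expect_error(compute_region_stats(pyr, matrix(1, 32, 32)), "geometry")
  expect_error(compute_region_stats(pyr, matrix(0, 64, 64)), "support")
  expect_error(stat_config(M = 4), "odd")
})
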