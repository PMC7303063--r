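test_that("letter arrays honor the grid and are seed-deterministic", {
  sp <- stimulus_spec("letter_array", grid = c(3, 4), seed = 7)
  la <- make_letter_array(sp)
  expect_equal(nrow(la$ground_truth), 12L)
  la2 <- make_letter_array(sp)
  expect_identical(la$image$pixels, la2$image$pixels)
  sp2 <- sp; sp2$seed <- 8
  expect_false(identical(la$image$pixels, make_letter_array(sp2)$image$pixels))
})

test_that("a single glyph lands centered on its cell", {
  sp <- stimulus_spec("letter_array", grid = c(1, 1), letters = "I", seed = 3)
  la <- make_letter_array(sp)
  ink <- pmax(sp$bg - la$image$pixels, 0)
  idx <- which(ink > 0, arr.ind = TRUE)
  wts <- ink[ink > 0]
  centroid <- c(sum((idx[, 1] - 1) * wts), sum((idx[, 2] - 1) * wts)) / sum(wts)
  expect_lt(max(abs(centroid - la$ground_truth[1, c("center_row", "center_col")])),
            0.5)
})

test_that("overlapping letters are rejected", {
  sp <- stimulus_spec("letter_array", item_deg = 2, spacing_deg = 1.5)
  expect_error(make_letter_array(sp), "overlap")
})

test_that("search arrays place exactly one target iff present", {
  sp <- stimulus_spec("search_array", n_items = 12, grid = c(4, 4), seed = 5)
  for (cond in c("feature_popout", "t_among_l", "conjunction")) {
    pres <- make_search_array(sp, cond, target_present = TRUE)
    abs_ <- make_search_array(sp, cond, target_present = FALSE)
    expect_equal(sum(pres$ground_truth$is_target), 1L)
    expect_equal(sum(abs_$ground_truth$is_target), 0L)
    expect_equal(nrow(pres$ground_truth), 12L)
  }
})

test_that("pop-out targets differ in orientation from every distractor", {
  sp <- stimulus_spec("search_array", n_items = 10, grid = c(4, 4), seed = 2)
  sa <- make_search_array(sp, "feature_popout", TRUE)
  gt <- sa$ground_truth
  expect_true(all(gt$angle[gt$is_target] != gt$angle[!gt$is_target]))
})

test_that("different seeds move the items", {
  sp1 <- stimulus_spec("search_array", n_items = 8, grid = c(4, 4), seed = 1)
  sp2 <- stimulus_spec("search_array", n_items = 8, grid = c(4, 4), seed = 2)
  g1 <- make_search_array(sp1, "t_among_l", TRUE)$ground_truth
  g2 <- make_search_array(sp2, "t_among_l", TRUE)$ground_truth
  pos1 <- as.matrix(g1[, c("center_row", "center_col")])
  pos2 <- as.matrix(g2[, c("center_row", "center_col")])
  # minimum pairwise displacement between the two position sets
  d <- sqrt(rowSums((pos1 - pos2)^2))
  expect_gt(min(d), 0)
})

test_that("infeasible item counts are rejected", {
  sp <- stimulus_spec("search_array", n_items = 20, grid = c(3, 3))
  expect_error(make_search_array(sp, "t_among_l"), "do not fit")
})

test_that("square arrays sit on a uniform gray field", {
  sp <- stimulus_spec("vwm_array", grid = c(3, 3), seed = 2)
  vw <- make_vwm_array(8, spec = sp)
  expect_equal(nrow(vw$ground_truth), 8L)
  expect_equal(dim(vw$raster)[3], 3L)
  empty <- make_vwm_array(0, spec = sp)
  expect_true(all(empty$raster == 0.5))
  expect_error(make_vwm_array(4, palette = matrix(numeric(0), 0, 3), spec = sp),
               "palette")
})

test_that("change pairs differ only inside the changed item", {
  sp <- stimulus_spec("vwm_array", grid = c(3, 3), seed = 2)
  cp <- make_change_pair(sp, item = 3, n_items = 8)
  d <- pmax(abs(cp$a$raster[, , 1] - cp$b$raster[, , 1]),
            abs(cp$a$raster[, , 2] - cp$b$raster[, , 2]),
            abs(cp$a$raster[, , 3] - cp$b$raster[, , 3]))
  idx <- which(d > 0, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  half <- sp$item_deg * sp$ppd / 2 + 2   # antialiasing margin
  expect_true(all(abs(idx[, 1] - 1 - cp$record$center_row) <= half))
  expect_true(all(abs(idx[, 2] - 1 - cp$record$center_col) <= half))
  # changed area is about one item's area
  area <- (sp$item_deg * sp$ppd)^2
  expect_lt(abs(nrow(idx) - area) / area, 0.35)
  # identity "change" is rejected
  old <- cp$a$ground_truth$color_index[3]
  expect_error(make_change_pair(sp, item = 3, new_color_index = old),
               "not a change")
})

test_that("ground truth is sufficient to re-render the stimulus", {
  sp <- stimulus_spec("vwm_array", grid = c(3, 3), seed = 6)
  a <- make_vwm_array(5, spec = sp)
  b <- foveatex:::render_vwm(a$ground_truth, as.matrix(sp$palette), sp)
  expect_identical(a$raster, b$raster)
})

test_that("noise textures are seeded, two-level, and grain-scaled", {
  t1 <- make_noise_texture(64, 64, ppd = 8, seed = 3)
  t2 <- make_noise_texture(64, 64, ppd = 8, seed = 3)
  expect_identical(t1$pixels, t2$pixels)
  expect_setequal(unique(as.vector(t1$pixels)), c(0.15, 0.85))
  # doubling the grain doubles the typical blob scale: compare lag-2
  # autocorrelation of coarse vs fine textures
  fine <- make_noise_texture(64, 64, ppd = 8, grain_deg = 0.125, seed = 4)
  coarse <- make_noise_texture(64, 64, ppd = 8, grain_deg = 0.5, seed = 4)
  lag2 <- function(img) cor(as.vector(img$pixels[, 1:62]),
                            as.vector(img$pixels[, 3:64]))
  expect_gt(lag2(coarse), lag2(fine))
})

test_that("crowding patches put the target at the requested eccentricity", {
  sp <- stimulus_spec("crowding_triplet", ppd = 8, seed = 1)
  cr <- make_crowding_patch(sp, ecc_deg = 10, jitter_deg = 0)
  gt <- cr$ground_truth
  tpos <- gt[gt$is_target, ]
  ecc <- sqrt(sum((c(tpos$center_row, tpos$center_col) -
                     cr$image$fixation)^2)) / 8
  expect_equal(ecc, 10, tolerance = 1e-6)
  expect_equal(nrow(gt), 3L)   # target + two flankers
  expect_error(make_crowding_patch(sp, ecc_deg = 10, field_deg = c(4, 6)),
               "exceeds")
})
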