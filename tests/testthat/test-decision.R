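test_that("hypothesis counting matches exhaustive subset enumeration", {
  expect_identical(mot_hypothesis_count(9, 4), 125L)
  expect_identical(mot_hypothesis_count(5, 5), 0L)
  expect_identical(mot_hypothesis_count(5, 2), oracle_subset_count(5, 2) - 1L)
  for (n in 1:12) for (k in c(0, 1, n %/% 2, n))
    expect_identical(mot_hypothesis_count(n, k), oracle_subset_count(n, k) - 1L)
  expect_error(mot_hypothesis_count(3, 4), "k <= n")
})

test_that("task composition multiplies class sets", {
  t2a <- gaussian_task(list(c(-1, 0), c(1, 0)))
  t2b <- gaussian_task(list(c(0, -1), c(0, 1)))
  t3 <- gaussian_task(list(-1, 0, 1))
  expect_length(compose_tasks(t2a, t2b)$classes, 4L)
  expect_length(compose_tasks(t2a, t3)$classes, 6L)
  one <- gaussian_task(list(c(0, 0)))
  expect_length(compose_tasks(t2a, one)$classes, 2L)
  # composed features concatenate
  comp <- compose_tasks(t2a, t2b)
  expect_equal(ncol(with_seed(1, comp$classes[[1]](3))), 4L)
})

test_that("task and budget constructors validate their inputs", {
  expect_error(task_spec(list(function(n) matrix(0, n, 1))), "named")
  expect_error(task_spec(list(a = 1)), "sampler")
  expect_error(task_spec(list(a = function(n) matrix(0, n, 1)),
                         priors = 1), NA)
  expect_error(complexity_budget("hyperplanes", 0), ">= 1")
  expect_error(complexity_budget("curvature", -1), "positive")
})

test_that("one hyperplane separates well-separated Gaussians near Bayes", {
  task <- gaussian_task(list(c(-2, 0), c(2, 0)))   # means 4 sd apart
  fit <- fit_budgeted_classifier(task, complexity_budget("hyperplanes", 1),
                                 n_train = 400, n_test = 2000, seed = 1)
  expect_gte(fit$accuracy, 0.95)   # Bayes accuracy is pnorm(2) ~ 0.977
})

test_that("XOR needs two hyperplanes", {
  xor_task <- task_spec(list(
    a = function(n) {
      s <- sample(c(-1, 1), n, TRUE)
      cbind(s * 2, s * 2) + matrix(rnorm(2 * n, sd = 0.5), n, 2)
    },
    b = function(n) {
      s <- sample(c(-1, 1), n, TRUE)
      cbind(s * 2, -s * 2) + matrix(rnorm(2 * n, sd = 0.5), n, 2)
    }))
  f1 <- fit_budgeted_classifier(xor_task, complexity_budget("hyperplanes", 1),
                                n_train = 800, n_test = 3000, seed = 2)
  f2 <- fit_budgeted_classifier(xor_task, complexity_budget("hyperplanes", 2),
                                n_train = 800, n_test = 3000, seed = 2)
  expect_lte(f1$accuracy, 0.80)
  expect_gte(f2$accuracy, 0.95)
})

test_that("unrestricted budgets reach the analytic Bayes accuracy", {
  # two spherical Gaussians 2 sd apart: Bayes accuracy pnorm(1)
  task <- gaussian_task(list(c(0, 0), c(2, 0)))
  fit <- fit_budgeted_classifier(task, complexity_budget("dimensions", Inf),
                                 n_train = 2000, n_test = 4000, seed = 3)
  expect_lt(abs(fit$accuracy - pnorm(1)), 0.02)
})

test_that("a dual task is no easier than its harder component", {
  t1 <- gaussian_task(list(c(-1.2, 0), c(1.2, 0)))
  t2 <- gaussian_task(list(c(0, -1.2), c(0, 1.2)))
  k <- complexity_budget("hyperplanes", 1)
  a1 <- fit_budgeted_classifier(t1, k, seed = 4)$accuracy
  a2 <- fit_budgeted_classifier(t2, k, seed = 4)$accuracy
  # the composed 4-class task under the same budget cannot beat the
  # better single task (with a small sampling allowance)
  dual <- compose_tasks(t1, t2)
  ad <- fit_budgeted_classifier(dual, k, seed = 4)$accuracy
  expect_lte(ad, min(a1, a2) + 0.02)
})

test_that("curvature-capped boundaries fit smooth tasks", {
  task <- gaussian_task(list(c(-1.5, 0), c(1.5, 0)))
  fit <- fit_budgeted_classifier(task, complexity_budget("curvature", 0.5),
                                 n_train = 400, n_test = 1000, seed = 5)
  expect_gt(fit$accuracy, 0.85)
})

test_that("working-memory change distances behave sensibly", {
  enc <- pixel_encoder()
  sp <- stimulus_spec("vwm_array", ppd = 8, item_deg = 1, spacing_deg = 1.8,
                      grid = c(3, 3), margin_deg = 0.6)
  # an array is at distance zero from itself
  a <- make_vwm_array(4, spec = sp)
  expect_equal(sqrt(sum((enc(a$raster) - enc(a$raster))^2)), 0)
  # one-item changes move the encoding less than recoloring every item
  one <- vapply(1:25, function(k) {
    s <- sp; s$seed <- k
    cp <- make_change_pair(s, item = 1, n_items = 8)
    sqrt(sum((enc(cp$a$raster) - enc(cp$b$raster))^2))
  }, numeric(1))
  all8 <- vapply(1:25, function(k) {
    s <- sp; s$seed <- k
    a <- make_vwm_array(8, spec = s)
    gt <- a$ground_truth
    gt$color_index <- ((gt$color_index + 3) %% 9) + 1
    b <- foveatex:::render_vwm(gt, as.matrix(s$palette), s)
    sqrt(sum((enc(a$raster) - enc(b$raster))^2))
  }, numeric(1))
  expect_lt(mean(one), mean(all8))
})

test_that("the confusability report honors its threshold limits", {
  enc <- pixel_encoder()
  sp <- stimulus_spec("vwm_array", ppd = 6, grid = c(3, 3))
  probes <- lapply(1:5, function(k) {
    s <- sp; s$seed <- k
    make_vwm_array(6, spec = s)$raster
  })
  r0 <- scene_confusability(enc, probes, threshold = 0)
  expect_true(all(vapply(seq_along(probes),
                         function(i) identical(r0$confusable[[i]], i), TRUE)))
  rInf <- scene_confusability(enc, probes, threshold = Inf)
  expect_true(all(lengths(rInf$confusable) == 5L))
  expect_error(scene_confusability(enc, list(), 1), "empty")
})

test_that("the change-derived precision separates perturbations from relayouts", {
  # peripherally viewed arrays: position jitter perturbs the encoding far
  # less than drawing a fresh layout, and fresh layouts always fall
  # outside the precision derived from one-item changes
  sp <- stimulus_spec("vwm_array", ppd = 6, item_deg = 1, spacing_deg = 2,
                      grid = c(3, 3), margin_deg = 0.6)
  dims <- ceiling((3 * 2 + 1.2) * 6)
  fix <- c((dims - 1) / 2, -8 * 6)   # array viewed at ~8 deg eccentricity
  enc <- stat_image_encoder(ppd = 6, fixation = fix,
                            config = stat_config(S = 2, O = 3, M = 3))
  vw <- vwm_experiment(enc, n_items_grid = 8, n_arrays = 8, spec = sp,
                       seed = 11)
  thr <- vw$mean_change_distance
  expect_gt(thr, 0)
  res <- vapply(1:12, function(k) {
    s <- sp; s$seed <- 4000 + k
    base <- make_vwm_array(8, spec = s)
    gtj <- base$ground_truth
    jit <- with_seed(s$seed + 1, matrix(runif(16, -0.1, 0.1) * sp$ppd, 8, 2))
    gtj$center_row <- gtj$center_row + jit[, 1]
    gtj$center_col <- gtj$center_col + jit[, 2]
    jittered <- foveatex:::render_vwm(gtj, as.matrix(s$palette), s)
    s2 <- s; s2$seed <- s$seed + 5000
    other <- make_vwm_array(8, spec = s2)
    e0 <- enc(base$raster)
    c(jit = sqrt(sum((e0 - enc(jittered$raster))^2)),
      oth = sqrt(sum((e0 - enc(other$raster))^2)))
  }, numeric(2))
  conf <- scene_confusability(enc, list(make_vwm_array(8, spec = sp)$raster),
                              threshold = thr)
  expect_identical(conf$confusable[[1]], 1L)
  expect_gte(mean(res["oth", ] > thr), 0.8)       # relayouts not confusable
  expect_gte(mean(res["jit", ] < res["oth", ]), 0.8)  # jitter is the smaller move
})
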