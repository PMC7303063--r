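test_that("analysis/synthesis is a tight frame (round trip to precision)", {
  set.seed(11)
  for (dims in list(c(64, 64), c(64, 96), c(128, 128))) {
    x <- matrix(runif(prod(dims)), dims[1], dims[2])
    p <- build_pyramid(x, S = 3, O = 4)
    expect_lt(max(abs(reconstruct_pyramid(p) - x)), 1e-10)
  }
})

test_that("band layout is dyadic and the trivial configuration is honored", {
  x <- matrix(runif(64 * 64), 64, 64)
  p <- build_pyramid(x, S = 3, O = 4)
  for (s in 1:3)
    expect_equal(dim(p$bands[[s]][[1]]), c(64, 64) / 2^(s - 1))
  p1 <- build_pyramid(x, S = 1, O = 1)
  expect_length(p1$bands, 1)
  expect_length(p1$bands[[1]], 1)
  expect_false(is.null(p1$highpass))
  expect_false(is.null(p1$lowpass_chain[[1]]))
})

test_that("a constant image has silent oriented bands and a flat lowpass", {
  p <- build_pyramid(matrix(0.7, 64, 64), S = 3, O = 4)
  for (s in 1:3) for (o in 1:4)
    expect_lt(max(band_magnitude(p, s, o)), 1e-12)
  expect_equal(mean(p$lowpass_chain[[3]]), 0.7, tolerance = 1e-12)
})

test_that("gratings concentrate energy in the matching orientation band", {
  n <- 128
  freq <- 0.12  # cycles/px, inside the first scale's passband
  vert <- matrix(0.5 + 0.4 * cos(2 * pi * freq * (0:(n - 1))), n, n,
                 byrow = TRUE)
  p <- build_pyramid(vert, S = 3, O = 4)
  e <- vapply(1:4, function(o) sum(band_magnitude(p, 1, o)^2), numeric(1))
  expect_equal(which.max(e), 1L)
  expect_gt(e[1] / sum(e), 0.5)
  # rotate 90 degrees: energy moves to the orthogonal band
  p2 <- build_pyramid(t(vert), S = 3, O = 4)
  e2 <- vapply(1:4, function(o) sum(band_magnitude(p2, 1, o)^2), numeric(1))
  expect_equal(which.max(e2), 3L)
})

test_that("the transform is linear", {
  set.seed(4)
  x <- matrix(rnorm(64 * 64), 64, 64)
  y <- matrix(rnorm(64 * 64), 64, 64)
  px <- build_pyramid(x, S = 3, O = 3)
  py <- build_pyramid(y, S = 3, O = 3)
  ps <- px
  for (s in 1:3) for (o in 1:3)
    ps$bands[[s]][[o]] <- px$bands[[s]][[o]] + py$bands[[s]][[o]]
  ps$highpass <- px$highpass + py$highpass
  ps$lowpass_chain[[3]] <- px$lowpass_chain[[3]] + py$lowpass_chain[[3]]
  expect_lt(max(abs(reconstruct_pyramid(ps) - (x + y))), 1e-10)
  # all-zero bands reconstruct to zero
  pz <- px
  for (s in 1:3) for (o in 1:3) pz$bands[[s]][[o]] <- px$bands[[s]][[o]] * 0
  pz$highpass <- px$highpass * 0
  pz$lowpass_chain[[3]] <- px$lowpass_chain[[3]] * 0
  expect_lt(max(abs(reconstruct_pyramid(pz))), 1e-12)
})

test_that("band magnitudes are non-negative and shift-equivariant", {
  set.seed(21)
  x <- matrix(runif(64 * 64), 64, 64)
  xs <- x[c(2:64, 1), ]   # shift one pixel
  p <- build_pyramid(x, S = 2, O = 4)
  ps <- build_pyramid(xs, S = 2, O = 4)
  for (o in 1:4) {
    m <- band_magnitude(p, 1, o)
    expect_true(all(m >= 0))
    msh <- band_magnitude(ps, 1, o)
    expect_gt(cor(as.vector(m[c(2:64, 1), ]), as.vector(msh)), 0.99)
  }
})

test_that("invalid configurations are rejected with guidance", {
  expect_error(build_pyramid(matrix(0.5, 16, 16), S = 4), "max feasible S=2")
  p <- build_pyramid(matrix(runif(64 * 64), 64, 64), S = 2, O = 3)
  expect_error(band_magnitude(p, 3, 1), "out of range")
  expect_error(band_magnitude(p, 1, 4), "out of range")
  p$bands[[2]][[3]] <- NULL
  expect_error(reconstruct_pyramid(p), "missing")
})
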