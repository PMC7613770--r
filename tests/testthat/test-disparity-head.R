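# Warp and cost-volume operators against brute-force oracles, cascade
# contracts, and differentiability of the full matching pipeline.

test_that("identity warp returns the source exactly", {
  set.seed(31)
  src <- array(rnorm(6 * 8 * 3), c(6, 8, 3))
  expect_identical(warp_right_to_left(src, matrix(0, 6, 8)), src)
})

test_that("integer-shift warp recovers the original columns", {
  set.seed(32)
  left <- array(rnorm(6 * 10 * 2), c(6, 10, 2))
  k <- 3L
  right <- array(0, dim(left))         # right(u) = left(u + k): contract r(x - d) = l(x)
  right[, 1:(10 - k), ] <- left[, (k + 1):10, ]
  rec <- warp_right_to_left(right, matrix(k, 6, 10))
  expect_equal(rec[, (k + 1):10, ], left[, (k + 1):10, ], tolerance = 1e-12)
})

test_that("warp matches the brute-force oracle for integer and fractional disparities", {
  set.seed(33)
  src <- array(rnorm(9 * 7 * 4), c(9, 7, 4))
  d_int <- matrix(sample(0:3, 63, replace = TRUE), 9, 7)
  expect_lt(max(abs(warp_right_to_left(src, d_int) - brute_force_warp(src, d_int))), 1e-6)
  d_frac <- matrix(runif(63, 0, 3), 9, 7)
  expect_lt(max(abs(warp_right_to_left(src, d_frac) - brute_force_warp(src, d_frac))), 1e-6)
})

test_that("cost volume equals the exhaustive oracle on small instances", {
  set.seed(34)
  for (trial in 1:3) {
    h <- sample(3:8, 1); w <- sample(3:8, 1); c <- sample(1:4, 1)
    l <- array(rnorm(h * w * c), c(h, w, c))
    r <- array(rnorm(h * w * c), c(h, w, c))
    cv <- build_cost_volume(l, r, -2:2)
    expect_lt(max(abs(cv - brute_force_cost_volume(l, r, -2:2))), 1e-6)
  }
  l <- array(rnorm(6 * 8 * 3), c(6, 8, 3))
  r <- array(rnorm(6 * 8 * 3), c(6, 8, 3))
  cv <- build_cost_volume(l, r, 0:10)
  expect_lt(max(abs(cv - brute_force_cost_volume(l, r, 0:10))), 1e-6)
})

test_that("constant features give v^2 costs in the interior", {
  v <- 0.7
  l <- array(v, c(5, 9, 3)); r <- array(v, c(5, 9, 3))
  cv <- build_cost_volume(l, r, -2:2)
  expect_equal(cv[3, 5, ], rep(v^2, 5), tolerance = 1e-12)
})

test_that("S6 volume has max_disparity/32 + 1 planes and rejects bad calls", {
  m <- tiny_model(heads = "disparity")
  expect_identical(m$layers$disparity$n_planes_s6, 11L)
  f6 <- array(rnorm(2 * 2 * 32), c(2, 2, 32))
  d6 <- estimate_scale(m, 6, f6, f6)
  expect_equal(dim(d6), c(2L, 2L))
  expect_true(all(is.finite(d6)))
  expect_error(estimate_scale(m, 6, f6, f6, matrix(0, 1, 1)), "absent")
  expect_error(build_cost_volume(f6, f6, integer(0)), "non-empty")
})

test_that("zeroed refinement tower reduces a cascade stage to learned upsampling", {
  m <- tiny_model(heads = "disparity")
  st <- m$layers$disparity$stages$s5
  for (p in surgstereo:::collect_params(st$tower)) p$value <- p$value * 0
  d_prev <- matrix(runif(4, 0.2, 0.8), 2, 2)   # at S6
  f5 <- array(rnorm(4 * 4 * 24), c(4, 4, 24))
  out <- estimate_scale(m, 5, f5, f5, d_prev)
  up2 <- surgstereo:::ag_upsample_x2(d_prev)
  expect_equal(out, 2 * up2, tolerance = 1e-12)
})

test_that("zeroed hourglass reduces full-resolution refinement to learned upscaling", {
  m <- tiny_model(heads = "disparity")
  for (p in surgstereo:::collect_params(m$layers$disparity$hourglass))
    p$value <- p$value * 0
  d2 <- matrix(runif(32 * 32, 1, 5), 32, 32)
  img <- random_image(64, 64, seed = 4)
  out <- refine_full_res(m, d2, img)
  expect_equal(dim(out), c(64L, 64L))
  expect_equal(out, 2 * surgstereo:::ag_upsample_x2(d2), tolerance = 1e-12)
})

test_that("full pyramid prediction obeys the shape law and is deterministic", {
  m <- tiny_model(heads = "disparity")
  left <- random_image(64, 64, seed = 5); right <- random_image(64, 64, seed = 6)
  p1 <- predict_disparity(m, left, right)
  expect_equal(dim(p1$disparity[[1]]), c(64L, 64L))
  expect_equal(dim(p1$disparity[[6]]), c(2L, 2L))
  expect_true(all(vapply(p1$disparity, function(d) all(is.finite(d)), logical(1))))
  p2 <- predict_disparity(m, left, right)
  expect_identical(p1, p2)
})

test_that("predictions stay finite across random weight initializations", {
  for (seed in 1:10) {
    m <- model_factory("lightweight", heads = "disparity", width_scale = 0.2,
                       seed = seed)
    p <- predict_disparity(m, random_image(64, 64, seed), random_image(64, 64, seed + 100))
    expect_true(all(vapply(p$disparity, function(d) all(is.finite(d)), logical(1))))
  }
})

test_that("the matching pipeline is differentiable w.r.t. the right features", {
  m <- tiny_model(heads = "disparity")
  set.seed(41)
  # move the zero-initialized regressor off its stationary point so the
  # gradient path through the cost volume is exercised
  out_layer <- m$layers$disparity$stages$s5$tower$out
  out_layer$W$value <- matrix(rnorm(length(out_layer$W$value), sd = 0.1),
                              nrow(out_layer$W$value), 1)
  f <- array(rnorm(4 * 4 * 24, sd = 0.5), c(4, 4, 24))
  d_prev <- matrix(runif(4, 0.2, 0.6), 2, 2)
  set_train_mode(m, TRUE)
  on.exit(set_train_mode(m, FALSE))
  err <- fd_grad_error(function(z)
    surgstereo:::ag_mean(surgstereo:::ag_square(
      estimate_scale(m, 5, f, z, d_prev))), f, eps = 1e-4)
  expect_lt(err, 1e-3)
  grad <- surgstereo:::ag_with_tape({
    zn <- surgstereo:::ag_input(f)
    loss <- surgstereo:::ag_mean(surgstereo:::ag_square(
      estimate_scale(m, 5, f, zn, d_prev)))
    surgstereo:::ag_backward(loss)
    zn$grad
  })
  expect_gt(max(abs(grad[, 2:3, ])), 0)   # interior pixels receive gradient
})
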