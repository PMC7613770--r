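# Closed-form loss values, masking rules, coefficient-collapse identities,
# and gradient flow through the self-supervised objective.

test_that("smooth L1 matches its closed form and is continuous at |w| = 1", {
  expect_equal(smooth_l1(0.5), 0.125)
  expect_equal(smooth_l1(2.0), 1.5)
  expect_equal(smooth_l1(1.0), 0.5)
  expect_equal(smooth_l1(-1.0), 0.5)
  w <- seq(-3, 3, by = 0.25)
  expect_equal(smooth_l1(w), ifelse(abs(w) < 1, 0.5 * w^2, abs(w) - 0.5))
})

test_that("supervised disparity loss is 0 for perfect predictions and 0.125 for a 0.5 offset", {
  gt <- matrix(runif(64 * 64, 2, 10), 64, 64)
  pyr <- list(gt)
  expect_equal(disparity_supervised_loss(pyr, gt), 0)
  expect_equal(disparity_supervised_loss(list(gt + 0.5), gt), 0.125)
})

test_that("ground truth beyond the search range contributes nothing", {
  set.seed(51)
  gt <- matrix(runif(64 * 64, 2, 10), 64, 64)
  pred <- gt + matrix(rnorm(64 * 64), 64, 64)
  gt_bad <- gt
  bad <- matrix(FALSE, 64, 64); bad[5:10, 7:12] <- TRUE
  gt_bad[bad] <- 321
  full <- disparity_supervised_loss(list(pred), gt_bad)
  masked <- disparity_supervised_loss(list(pred), gt, valid = !bad)
  expect_equal(full, masked)
})

test_that("multi-scale supervision up-samples and up-scales before comparing", {
  gt <- matrix(6, 64, 64)
  half <- matrix(3, 32, 32)        # perfect S2 prediction in S2 units
  expect_equal(disparity_supervised_loss(list(half), gt), 0)
  expect_warning(z <- disparity_supervised_loss(list(half), gt,
                                                valid = matrix(FALSE, 64, 64)),
                 "no valid")
  expect_equal(z, 0)
})

test_that("weighted BCE matches hand arithmetic and decomposes by class", {
  expect_equal(wbce(matrix(1, 1, 1), matrix(0.5, 1, 1), beta = 2),
               2 * (-log(0.5)), tolerance = 1e-12)
  s <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(wbce(s, s, beta = 3), 1e-5)
  expect_error(wbce(s, s, beta = 0), "positive")
  set.seed(52)
  s8 <- matrix(rbinom(64, 1, 0.3), 8, 8)
  p8 <- matrix(runif(64, 0.05, 0.95), 8, 8)
  fg <- function(beta) -mean(beta * s8 * log(p8))
  bg <- -mean((1 - s8) * log(1 - p8))
  expect_equal(wbce(s8, p8, 2), fg(2) + bg)
  expect_equal(wbce(s8, p8, 4) - bg, 2 * (wbce(s8, p8, 2) - bg), tolerance = 1e-12)
})

test_that("soft dice covers the identical, disjoint and empty cases", {
  ones <- matrix(1, 4, 4)
  expect_equal(soft_dice_loss(ones, ones), 0)
  a <- matrix(0, 4, 4); a[, 1:2] <- 1
  b <- matrix(0, 4, 4); b[, 3:4] <- 1
  expect_equal(soft_dice_loss(a, b), 1 - 1e-5 / (16 + 1e-5), tolerance = 1e-12)
  zero <- matrix(0, 4, 4)
  expect_equal(soft_dice_loss(zero, zero), 0)
})

test_that("segmentation loss is the equal mix and decreases toward the target", {
  set.seed(53)
  s <- matrix(rbinom(64, 1, 0.3), 8, 8)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  w <- loss_weights()
  expect_equal(segmentation_loss(s, p, w),
               0.5 * wbce(s, p, w$beta_wbce) + 0.5 * soft_dice_loss(s, p))
  target <- pmin(pmax(s, 1e-4), 1 - 1e-4)
  vals <- vapply(c(0, 0.5, 1), function(t)
    segmentation_loss(s, (1 - t) * p + t * target, w), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM loss is 0 on identical images and matches the constant-image value", {
  img <- random_image(32, 32, seed = 54)
  expect_lt(abs(ssim_loss(img, img)), 1e-12)
  a <- array(0.2, c(32, 32, 3)); b <- array(0.8, c(32, 32, 3))
  # constants in, zero variances: SSIM = (2*0.16 + 1e-4)/(0.04 + 0.64 + 1e-4)
  expected <- (1 - (2 * 0.2 * 0.8 + 1e-4) / (0.2^2 + 0.8^2 + 1e-4)) / 2
  expect_equal(ssim_loss(a, b), expected, tolerance = 1e-12)
  expect_equal(expected, 0.2646669, tolerance = 1e-6)
  for (seed in 1:3) {
    u <- random_image(16, 16, seed); v <- random_image(16, 16, seed + 10)
    l <- ssim_loss(u, v)
    expect_gte(l, 0); expect_lte(l, 1)
  }
  expect_error(ssim_loss(random_image(8, 8), random_image(8, 8)), "window")
})

test_that("photometric loss follows the smooth-L1 composition", {
  a <- random_image(16, 16, seed = 55)
  expect_equal(photometric_loss(a, a), 0)
  expect_equal(photometric_loss(a, a + 0.5), 0.125)
  b <- random_image(16, 16, seed = 56)
  expect_equal(photometric_loss(a, b), mean(smooth_l1(a - b)))
})

test_that("smoothness loss: zero on constants, s/320 on a ramp, edge-damped", {
  img_const <- array(0.4, c(16, 16, 3))
  expect_equal(smoothness_loss(img_const, matrix(7, 16, 16)), 0)
  s <- 2.5
  ramp <- matrix(rep(seq_len(16) * s, each = 16), 16, 16)
  expect_equal(smoothness_loss(img_const, ramp), s / 320, tolerance = 1e-12)
  # doubling image contrast never increases the loss
  set.seed(57)
  base <- random_image(16, 16, seed = 57)
  lo <- 0.5 + 0.1 * (base - 0.5); hi <- 0.5 + 0.2 * (base - 0.5)
  expect_lte(smoothness_loss(hi, ramp), smoothness_loss(lo, ramp))
})

test_that("self-supervised loss collapses to its parts under extreme coefficients", {
  s <- generate_fronto_scene(64, 64, 6.0, 11)
  w_ph <- loss_weights(alpha_ss = 1, beta_ss = 1)
  warped <- warp_right_to_left(s$right, s$disparity)
  expect_equal(self_supervised_disparity_loss(s$left, s$right, s$disparity, w_ph),
               photometric_loss(s$left, warped))
  w <- loss_weights()
  ph <- photometric_loss(s$left, warped)
  ss <- ssim_loss(s$left, warped, w)
  sm <- smoothness_loss(s$left, s$disparity, w$max_disparity)
  expect_equal(self_supervised_disparity_loss(s$left, s$right, s$disparity, w),
               0.7 * (0.9 * ph + 0.1 * ss) + 0.3 * sm)
  # ground-truth disparity drives the photometric term to (near) zero away
  # from the no-correspondence band (zero-filled leftmost columns)
  interior <- s$left[, 7:64, , drop = FALSE]
  interior_w <- warped[, 7:64, , drop = FALSE]
  expect_lt(photometric_loss(interior, interior_w), 1e-3)
})

test_that("multi-task combination is the stated convex mix", {
  expect_equal(multitask_loss(1.0, 0.0, 0.2), 0.2)
  expect_equal(multitask_loss(0.0, 1.0, 0.2), 0.8)
  for (a in c(0.1, 0.5, 0.9)) expect_equal(multitask_loss(0.5, 0.5, a), 0.5)
})

test_that("self-supervised loss gradients w.r.t. disparity match finite differences", {
  set.seed(58)
  s <- generate_fronto_scene(64, 64, 4.0, 13)
  sub <- list(left = s$left[1:32, 1:32, , drop = FALSE],
              right = s$right[1:32, 1:32, , drop = FALSE])
  d0 <- matrix(runif(6 * 6, 1, 3), 6, 6)
  w <- loss_weights(ssim_window = 5)
  fwd <- function(z) self_supervised_disparity_loss(
    sub$left[1:6, 1:6, , drop = FALSE], sub$right[1:6, 1:6, , drop = FALSE], z, w)
  expect_lt(fd_grad_error(fwd, d0, eps = 1e-5), 1e-3)
})
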