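# Metric definitions, boundary conventions and invariances.

test_that("EPE covers exact, offset and averaged cases", {
  gt <- matrix(runif(32 * 32, 1, 20), 32, 32)
  expect_equal(epe(gt, gt), 0)
  expect_equal(epe(gt + 1, gt), 1.0)
  pred <- gt; pred[, 1:16] <- pred[, 1:16] + 2
  expect_equal(epe(pred, gt), 1.0)
  expect_error(epe(gt, gt, matrix(FALSE, 32, 32)), "valid")
})

test_that("Bad3 uses a strict 3-pixel threshold", {
  gt <- matrix(5, 8, 8)
  expect_equal(bad3(gt + 4, gt), 100.0)
  expect_equal(bad3(gt + 3, gt), 0.0)
  pred <- gt
  pred[1, 1:2] <- gt[1, 1:2] + 10
  v <- matrix(FALSE, 8, 8); v[1, 1:8] <- TRUE
  expect_equal(bad3(pred, gt, v), 25.0)
})

test_that("disparity-to-depth conversion follows f*B/d with a validity floor", {
  rig <- camera_rig(1000, 5)
  d <- matrix(c(50, 0, 25, 100), 2, 2)
  out <- disparity_to_depth(d, rig)
  expect_equal(out$depth[1, 1], 100)
  expect_equal(out$depth[2, 2], 50)
  expect_false(out$valid[2, 1])          # zero disparity is not convertible
  expect_true(is.na(out$depth[2, 1]))
  half <- disparity_to_depth(d / 2, rig)
  expect_equal(half$depth[1, 1], 200)    # halving disparity doubles depth
  expect_error(camera_rig(0, 5), "positive")
})

test_that("depth MAE agrees with EPE-style arithmetic on generator output", {
  s <- generate_smooth_scene(64, 64, 8, 24, 9)
  rig <- camera_rig(800, 4.2)
  gt_depth <- disparity_to_depth(s$disparity, rig)
  pred_depth <- disparity_to_depth(s$disparity + 1, rig)
  expect_equal(depth_mae(gt_depth$depth, gt_depth$depth), 0)
  expect_equal(depth_mae(gt_depth$depth + 2, gt_depth$depth), 2.0)
  joint <- s$valid & gt_depth$valid & pred_depth$valid
  manual <- mean(abs(pred_depth$depth[joint] - gt_depth$depth[joint]))
  expect_equal(depth_mae(pred_depth$depth, gt_depth$depth, joint), manual)
})

test_that("IoU counts intersection over union with the both-empty convention", {
  a <- matrix(FALSE, 8, 8); a[2:3, 2:5] <- TRUE
  expect_equal(iou(a, a), 1.0)
  b <- matrix(FALSE, 8, 8); b[6:7, 2:5] <- TRUE
  expect_equal(iou(a, b), 0.0)
  x <- matrix(FALSE, 8, 8); x[1, 1:8] <- TRUE
  y <- matrix(FALSE, 8, 8); y[1, 5:8] <- TRUE; y[2, 1:4] <- TRUE
  expect_equal(iou(x, y), 4 / 12)
  empty <- matrix(FALSE, 8, 8)
  expect_equal(iou(empty, empty), 1.0)
  expect_error(iou(a, matrix(FALSE, 4, 4)), "shape")
})

test_that("the coverage filter strictly exceeds its threshold", {
  all_valid <- matrix(TRUE, 10, 10)
  expect_true(coverage_filter(all_valid))
  ten_pct <- matrix(FALSE, 10, 10); ten_pct[1, ] <- TRUE
  expect_false(coverage_filter(ten_pct))       # exactly 10% does not pass
  expect_false(coverage_filter(matrix(FALSE, 10, 10)))
})

test_that("metrics are invariant under simultaneous horizontal flips", {
  set.seed(71)
  gt <- matrix(runif(64, 1, 10), 8, 8)
  pred <- gt + matrix(rnorm(64, sd = 3), 8, 8)
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  expect_equal(bad3(pred, gt), bad3(flip(pred), flip(gt)))
  expect_equal(epe(pred, gt), epe(flip(pred), flip(gt)))
  ma <- matrix(runif(64) > 0.6, 8, 8); mb <- matrix(runif(64) > 0.6, 8, 8)
  expect_equal(iou(ma, mb), iou(flip(ma), flip(mb)))
})

test_that("frame evaluation applies the coverage filter before aggregating", {
  gt <- matrix(5, 16, 16)
  sparse_valid <- matrix(FALSE, 16, 16); sparse_valid[1, 1:16] <- TRUE  # 6.25%
  frames <- list(
    list(pred = gt + 1, gt = gt, valid = matrix(TRUE, 16, 16)),
    list(pred = gt + 9, gt = gt, valid = sparse_valid)
  )
  rep <- evaluate_frames(frames, rig = camera_rig(1000, 5))
  expect_equal(rep$n_evaluated, 1L)
  expect_equal(rep$epe, 1.0)
  expect_gt(rep$depth_mae, 0)
})
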