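# Generators: rectification round trips, determinism, range contracts,
# and the tool-mask coverage statistic.

test_that("zero-shift fronto scene is the identity pair", {
  s <- generate_fronto_scene(64, 64, 0.0, 7)
  expect_equal(s$right, s$left)
  expect_true(all(s$disparity == 0))
  expect_true(all(s$valid))
})

test_that("fronto round trip is exact on valid pixels (integer and fractional shifts)", {
  for (shift in c(8.0, 12.5)) {
    s <- generate_fronto_scene(64, 64, shift, 7)
    rec <- warp_right_to_left(s$right, s$disparity)
    v3 <- array(rep(s$valid, 3), dim(s$left))
    expect_lt(mean(abs(rec - s$left)[v3]), 0.02)
    expect_false(any(s$valid[, seq_len(ceiling(shift))]))
    expect_true(all(s$valid[, (ceiling(shift) + 1):64]))
  }
})

test_that("generators are deterministic under a fixed seed", {
  a <- generate_fronto_scene(64, 96, 8.0, 7)
  b <- generate_fronto_scene(64, 96, 8.0, 7)
  expect_identical(a, b)
  c1 <- generate_smooth_scene(96, 96, 4, 24, 3)
  c2 <- generate_smooth_scene(96, 96, 4, 24, 3)
  expect_identical(c1, c2)
  m1 <- generate_instrument_mask(128, 160, 2, 5)
  m2 <- generate_instrument_mask(128, 160, 2, 5)
  expect_identical(m1, m2)
})

test_that("smooth scene honors the disparity range and the photometric contract", {
  s <- generate_smooth_scene(96, 96, 4, 24, 3)
  expect_gte(min(s$disparity), 4)
  expect_lte(max(s$disparity), 24)
  rec <- warp_right_to_left(s$right, s$disparity)
  v3 <- array(rep(s$valid, 3), dim(s$left))
  expect_lt(mean(abs(rec - s$left)[v3]), 0.02)
})

test_that("collapsed disparity range degenerates to a fronto-parallel scene", {
  s <- generate_smooth_scene(64, 64, 4, 4, 3)
  expect_true(all(s$disparity == 4))
})

test_that("out-of-range generator arguments are rejected", {
  expect_error(generate_fronto_scene(64, 64, 33, 1), "range")
  expect_error(generate_fronto_scene(64, 64, -1, 1), "range")
  expect_error(generate_smooth_scene(64, 64, 4, 321, 1), "range|\\[0, 320\\]")
  expect_error(generate_fronto_scene(60, 64, 4, 1), "divisible")
})

test_that("instrument masks are border-entering elongated blobs", {
  expect_true(all(!generate_instrument_mask(64, 64, 0, 1)))
  m <- generate_instrument_mask(128, 160, 2, 5)
  expect_type(m, "logical")
  expect_equal(dim(m), c(128L, 160L))
  # every connected component touches a border: flood from the border and
  # verify no foreground is left
  reach <- m & FALSE
  frontier <- m & FALSE
  frontier[1, ] <- m[1, ]; frontier[128, ] <- m[128, ]
  frontier[, 1] <- m[, 1]; frontier[, 160] <- m[, 160]
  reach <- frontier
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-128, ]
    grown[-128, ] <- grown[-128, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -160]
    grown[, -160] <- grown[, -160] | reach[, -1]
    grown <- grown & m
    if (identical(grown, reach)) break
    reach <- grown
  }
  expect_identical(reach, m)
})

test_that("mean tool coverage over many seeds is near the 15% statistic", {
  fractions <- vapply(0:199, function(sd)
    mean(generate_instrument_mask(256, 320, 2, sd)), numeric(1))
  expect_gte(mean(fractions), 0.10)
  expect_lte(mean(fractions), 0.20)
})

test_that("stored disparities stay inside the configured search range", {
  for (seed in 1:5) {
    s <- generate_smooth_scene(64, 96, 0, 320, seed)
    expect_gte(min(s$disparity), 0)
    expect_lte(max(s$disparity), 320)
    expect_true(all(is.finite(s$disparity[s$valid])))
  }
})
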