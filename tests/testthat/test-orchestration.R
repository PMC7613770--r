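# Training orchestration: augmentation contracts, the phased training loop,
# optimizer null updates, model modularity and checkpoint interchange.

test_that("augmentation keeps the rectification contract under vertical flips", {
  s <- generate_fronto_scene(64, 96, 8.0, 17)   # integer shift: exact gather
  cfg <- train_config("pretrain", crop = c(64, 32), vflip_prob = 1,
                      norm_mean = rep(0, 3), norm_std = rep(1, 3))
  a <- augment_sample(s, cfg, seed = 5)
  expect_equal(dim(a$left), c(32L, 64L, 3L))
  rec <- warp_right_to_left(a$right, a$disparity)
  # the crop's leftmost ceiling(d) columns lose their correspondence to the
  # cropped right view; the contract holds everywhere else
  ok <- a$valid; ok[, 1:8] <- FALSE
  v3 <- array(rep(ok, 3), dim(a$left))
  expect_lt(mean(abs(rec - a$left)[v3]), 1e-9)
})

test_that("cropping preserves disparity values and augmentation is seed-deterministic", {
  s <- generate_fronto_scene(64, 96, 9.0, 18)
  cfg <- train_config("pretrain", crop = c(32, 32), vflip_prob = 0.5,
                      norm_mean = rep(0.5, 3), norm_std = rep(0.5, 3))
  a1 <- augment_sample(s, cfg, seed = 3)
  a2 <- augment_sample(s, cfg, seed = 3)
  expect_identical(a1, a2)
  expect_true(all(a1$disparity == 9.0))
  expect_error(augment_sample(s, train_config("pretrain", crop = c(128, 128)), 1),
               "crop")
  expect_error(train_config("pretrain", crop = c(33, 32)), "divisible")
})

test_that("zero learning rate leaves every weight bit-identical", {
  m <- tiny_model(heads = "disparity")
  before <- lapply(surgstereo:::collect_params(m$layers), function(p) p$value)
  data <- list(generate_fronto_scene(64, 64, 6, 1), generate_fronto_scene(64, 64, 9, 2))
  cfg <- train_config("pretrain", epochs = 1, batch_size = 2,
                      lr_schedule = "constant", max_lr = 0,
                      norm_mean = rep(0.5, 3), norm_std = rep(0.5, 3))
  run_phase(m, data, cfg)
  after <- lapply(surgstereo:::collect_params(m$layers), function(p) p$value)
  expect_identical(before, after)
})

test_that("phase/dataset mismatches fail before any training step", {
  m <- tiny_model()
  no_gt <- list(stereo_sample(random_image(64, 64), random_image(64, 64)))
  expect_error(run_phase(m, no_gt, train_config("pretrain")), "disparity ground truth")
  expect_error(run_phase(m, no_gt, train_config("finetune_seg")), "masks")
  m_seg <- tiny_model(heads = "segmentation")
  s <- generate_fronto_scene(64, 64, 5, 1)
  expect_error(run_phase(m_seg, list(s), train_config("pretrain")), "disparity head")
})

test_that("multitask objective reads only the S1 disparity output", {
  w <- loss_weights()
  s <- generate_fronto_scene(64, 64, 5, 23)
  base <- self_supervised_disparity_loss(s$left, s$right, s$disparity, w)
  pyr <- list(disparity = c(list(s$disparity),
                            lapply(2:6, function(i)
                              matrix(99, 64 / 2^(i - 1), 64 / 2^(i - 1)))))
  # perturbing every coarser entry leaves the S1-only objective unchanged
  expect_equal(self_supervised_disparity_loss(s$left, s$right,
                                              pyr$disparity[[1]], w), base)
})

test_that("segmentation fine-tuning decreases the loss on fixture masks", {
  set.seed(101)
  decreasing <- 0L
  for (seed in 0:2) {
    m <- model_factory("lightweight", heads = c("disparity", "segmentation"),
                       width_scale = 0.2, seed = 100 + seed)
    data <- lapply(1:3, function(i) {
      s <- generate_fronto_scene(64, 64, 5, seed * 10 + i)
      s$mask <- generate_instrument_mask(64, 64, 2, seed * 10 + i)
      s
    })
    cfg <- train_config("finetune_seg", epochs = 10, batch_size = 3,
                        lr_schedule = "constant", max_lr = 1e-3,
                        norm_mean = rep(0.5, 3), norm_std = rep(0.5, 3),
                        seed = seed)
    res <- run_phase(m, data, cfg)
    n <- length(res$step_losses)
    first <- mean(res$step_losses[1:3])
    last <- mean(res$step_losses[(n - 2):n])
    if (last < first) decreasing <- decreasing + 1L
  }
  expect_gte(decreasing, 2L)
})

test_that("single-task fine-tuning leaves the other head's weights untouched", {
  m <- tiny_model()
  disp_before <- lapply(surgstereo:::collect_params(m$layers$disparity),
                        function(p) p$value)
  data <- lapply(1:2, function(i) {
    s <- generate_fronto_scene(64, 64, 6, i)
    s$mask <- generate_instrument_mask(64, 64, 1, i)
    s
  })
  cfg <- train_config("finetune_seg", epochs = 1, batch_size = 2,
                      lr_schedule = "constant", max_lr = 1e-3,
                      norm_mean = rep(0.5, 3), norm_std = rep(0.5, 3))
  run_phase(m, data, cfg)
  disp_after <- lapply(surgstereo:::collect_params(m$layers$disparity),
                       function(p) p$value)
  expect_identical(disp_before, disp_after)
  seg_after <- surgstereo:::collect_params(m$layers$segmentation)
  expect_false(identical(lapply(seg_after, function(p) p$value),
                         lapply(surgstereo:::collect_params(
                           tiny_model()$layers$segmentation), function(p) p$value)))
})

test_that("removing one head never changes the other head's outputs", {
  img_l <- random_image(64, 64, seed = 1); img_r <- random_image(64, 64, seed = 2)
  both <- tiny_model(seed = 11)
  disp_only <- tiny_model(heads = "disparity", seed = 11)
  seg_only <- tiny_model(heads = "segmentation", seed = 11)
  load_state_dict(disp_only, state_dict(both))
  load_state_dict(seg_only, state_dict(both))
  expect_identical(predict_disparity(both, img_l, img_r),
                   predict_disparity(disp_only, img_l, img_r))
  expect_identical(predict_mask(both, img_l)$logits,
                   predict_mask(seg_only, img_l)$logits)
})

test_that("checkpoints interchange between single- and multi-head models", {
  disp_only <- tiny_model(heads = "disparity", seed = 12)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(disp_only, f)
  multi <- tiny_model(seed = 13)
  seg_init <- lapply(surgstereo:::collect_params(multi$layers$segmentation),
                     function(p) p$value)
  load_checkpoint(multi, f)
  img_l <- random_image(64, 64, seed = 3); img_r <- random_image(64, 64, seed = 4)
  expect_identical(predict_disparity(multi, img_l, img_r),
                   predict_disparity(disp_only, img_l, img_r))
  seg_now <- lapply(surgstereo:::collect_params(multi$layers$segmentation),
                    function(p) p$value)
  expect_identical(seg_now, seg_init)     # untouched head stays at init
  other <- model_factory("resnet34", heads = "segmentation", seed = 1)
  expect_error(load_checkpoint(other, f), "variant")
})

test_that("a segmentation-only model consumes just the left view", {
  m <- tiny_model(heads = "segmentation", seed = 14)
  expect_error(predict_disparity(m, random_image(64, 64), random_image(64, 64)),
               "disparity head")
  out <- predict_mask(m, random_image(64, 64, seed = 5))
  expect_equal(dim(out$logits), c(64L, 64L))
  expect_error(model_factory("lightweight", heads = character(0)), "head")
})
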