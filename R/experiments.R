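# Small-scale reproducible studies: the desk-scale stand-ins for the
# published training phases, fully driven by one integer seed.

#' Supervised disparity recovery on synthetic fronto-parallel scenes
#'
#' Trains a width-reduced lightweight disparity model from scratch on
#' constant-shift random-dot stereo pairs (shifts drawn uniformly from
#' 4–28 px at 64x64) with full multi-scale supervision, then reports the
#' end-point error of the full-resolution output on held-out scenes.
#' All randomness (scene shifts, textures, initialization, data order)
#' derives from `seed`.
#'
#' @param seed integer master seed
#' @param n_train,n_test number of training / held-out scenes
#' @param epochs one-cycle epochs at batch size 1
#' @param max_lr peak learning rate
#' @param width_scale model capacity multiplier
#' @return list with `epe` (held-out, full resolution), `per_scale_epe`,
#'   `model`, and the training `log`
#' @export
experiment_disparity_recovery <- function(seed, n_train = 200L, n_test = 20L,
                                          epochs = 7L, max_lr = 1e-2,
                                          width_scale = 0.25) {
  seed <- as.integer(seed)
  shifts_tr <- with_local_seed(seed, stats::runif(n_train, 4, 28))
  train <- lapply(seq_len(n_train), function(i)
    generate_fronto_scene(64, 64, shifts_tr[i], seed * 1000L + i))
  shifts_te <- with_local_seed(seed + 1L, stats::runif(n_test, 4, 28))
  test <- lapply(seq_len(n_test), function(i)
    generate_fronto_scene(64, 64, shifts_te[i], seed * 1000L + 500000L + i))

  model <- model_factory("lightweight", heads = "disparity",
                         width_scale = width_scale, seed = seed + 2L)
  cfg <- train_config("pretrain", epochs = epochs, batch_size = 1L,
                      lr_schedule = "one_cycle", max_lr = max_lr,
                      vflip_prob = 0,   # flips only add gradient variance here
                      norm_mean = rep(0.5, 3), norm_std = rep(0.5, 3),
                      width_scale = width_scale, seed = seed + 3L)
  fit <- run_phase(model, train, cfg)

  set_train_mode(model, FALSE)
  per_scale <- matrix(0, n_test, 6)
  for (j in seq_len(n_test)) {
    s <- test[[j]]
    l <- normalize_image(s$left, cfg$norm_mean, cfg$norm_std)
    r <- normalize_image(s$right, cfg$norm_mean, cfg$norm_std)
    pyr <- predict_disparity(model, l, r)
    for (sc in 1:6) {
      d <- pyr$disparity[[sc]]
      ratio <- nrow(s$disparity) / nrow(d)
      full <- if (ratio > 1) resize_bilinear(d, nrow(s$disparity), ncol(s$disparity)) * ratio else d
      per_scale[j, sc] <- epe(full, s$disparity, s$valid)
    }
  }
  list(epe = mean(per_scale[, 1]), per_scale_epe = colMeans(per_scale),
       model = model, log = fit$log)
}

#' Self-supervised adaptation on fresh scenes
#'
#' Starting from a trained disparity model (optionally with perturbed
#' weights), fine-tunes with the self-supervised stereo loss only (no
#' ground truth) on newly generated scenes and reports the held-out EPE
#' before and after.
#' @param model a trained disparity model (modified in place)
#' @param seed integer seed for the adaptation scenes
#' @param n_scenes,epochs adaptation problem size
#' @param max_lr constant learning rate
#' @param perturb_sd if positive, Gaussian noise of this sd is added to all
#'   weights before adapting (recovery scenario)
#' @return list with `epe_before`, `epe_after`
#' @export
experiment_self_supervised_adaptation <- function(model, seed, n_scenes = 30L,
                                                  epochs = 2L, max_lr = 2e-4,
                                                  perturb_sd = 0) {
  seed <- as.integer(seed)
  if (perturb_sd > 0) {
    with_local_seed(seed + 7L, {
      for (p in collect_params(model$layers))
        p$value <- p$value + stats::rnorm(length(p$value), sd = perturb_sd)
    })
  }
  shifts <- with_local_seed(seed, stats::runif(n_scenes, 4, 28))
  scenes <- lapply(seq_len(n_scenes), function(i)
    generate_fronto_scene(64, 64, shifts[i], seed * 1000L + 700000L + i))
  shifts_te <- with_local_seed(seed + 1L, stats::runif(10, 4, 28))
  test <- lapply(seq_len(10L), function(i)
    generate_fronto_scene(64, 64, shifts_te[i], seed * 1000L + 800000L + i))
  norm <- function(img) normalize_image(img, rep(0.5, 3), rep(0.5, 3))
  heldout <- function() {
    set_train_mode(model, FALSE)
    mean(vapply(test, function(s) {
      pyr <- predict_disparity(model, norm(s$left), norm(s$right))
      epe(pyr$disparity[[1]], s$disparity, s$valid)
    }, numeric(1)))
  }
  epe_before <- heldout()

  w <- loss_weights()
  params <- collect_params(model$layers)
  opt <- adamw(params, weight_decay = 1e-4)
  set_train_mode(model, TRUE)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_local_seed(seed + 10L + ep, sample.int(n_scenes))
    for (j in ord) {
      s <- scenes[[j]]
      ag_with_tape({
        pyr <- predict_disparity(model, norm(s$left), norm(s$right))
        loss <- self_supervised_disparity_loss(norm(s$left), norm(s$right),
                                               pyr$disparity[[1L]], w)
        ag_backward(loss)
      })
      step <- step + 1L
      opt$step(max_lr)
    }
  }
  list(epe_before = epe_before, epe_after = heldout())
}

#' Segmentation overfit study on generated instrument masks
#'
#' Trains a width-reduced segmentation model on a handful of generated
#' capsule masks until it reproduces them, reporting the IoU against the
#' training masks — a capacity/plumbing check for the decoder and losses.
#' @param seed integer master seed
#' @param n_masks number of training masks
#' @param epochs one-cycle epochs at batch size 1
#' @param max_lr peak learning rate
#' @param width_scale model capacity multiplier
#' @return list with `iou` (mean over masks), `per_mask_iou`, `model`
#' @export
experiment_segmentation_overfit <- function(seed, n_masks = 5L, epochs = 250L,
                                            max_lr = 5e-3, width_scale = 0.4) {
  seed <- as.integer(seed)
  data <- lapply(seq_len(n_masks), function(i) {
    s <- generate_fronto_scene(64, 64, 8, seed * 100L + i)
    s$mask <- generate_instrument_mask(64, 64, 2L, seed * 100L + i)
    s
  })
  model <- model_factory("lightweight", heads = "segmentation",
                         width_scale = width_scale, seed = seed + 1L)
  cfg <- train_config("finetune_seg", epochs = epochs, batch_size = 1L,
                      lr_schedule = "one_cycle", max_lr = max_lr,
                      vflip_prob = 0,      # pure memorization study
                      norm_mean = rep(0.5, 3), norm_std = rep(0.5, 3),
                      width_scale = width_scale, seed = seed + 2L)
  run_phase(model, data, cfg)
  set_train_mode(model, FALSE)
  ious <- vapply(data, function(s) {
    p <- predict_mask(model, normalize_image(s$left, cfg$norm_mean, cfg$norm_std))
    iou(p$mask, s$mask)
  }, numeric(1))
  list(iou = mean(ious), per_mask_iou = ious, model = model)
}
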