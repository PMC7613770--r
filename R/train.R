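# Orchestration: model assembly, data augmentation, the AdamW optimizer,
# learning-rate schedules and the phased training loop
# (pretrain -> multitask -> single-task fine-tuning).

#' Assemble a model with the requested heads
#'
#' Builds the shared encoder plus any subset of the disparity and
#' segmentation heads.  Single-head models share the encoder parameter
#' layout with multi-task models, so checkpoints interchange: loading a
#' disparity-only checkpoint into a multi-task model leaves the segmentation
#' head at its initialization.
#'
#' @param variant `"lightweight"` or `"resnet34"`
#' @param heads non-empty subset of `c("disparity", "segmentation")`
#' @param max_disparity disparity search range (pixels; S6 gets
#'   `max_disparity/32 + 1` cost planes)
#' @param width_scale capacity multiplier for the lightweight variant and the
#'   head towers (1 reproduces the published architecture)
#' @param seed integer seed for weight initialization
#' @return a model environment with `$layers`, `$variant`, `$heads`,
#'   `$training`
#' @export
model_factory <- function(variant = c("lightweight", "resnet34"),
                          heads = c("disparity", "segmentation"),
                          max_disparity = 320, width_scale = 1, seed = 42L) {
  variant <- match.arg(variant)
  if (length(heads) == 0) stop("at least one head is required")
  heads <- match.arg(heads, c("disparity", "segmentation"), several.ok = TRUE)
  widths <- encoder_widths(variant, width_scale)
  model <- new.env(parent = emptyenv())
  model$variant <- variant
  model$heads <- heads
  model$max_disparity <- max_disparity
  model$width_scale <- width_scale
  model$training <- FALSE
  with_local_seed(seed, {
    layers <- list(encoder = if (variant == "resnet34") build_resnet34_encoder()
                   else build_lightweight_encoder(widths))
    if ("disparity" %in% heads)
      layers$disparity <- build_disparity_head(widths, width_scale, max_disparity)
    if ("segmentation" %in% heads)
      layers$segmentation <- build_segmentation_head(widths)
    model$layers <- layers
  })
  class(model) <- c("stereo_model", class(model))
  model
}

#' Switch a model between training and evaluation mode
#'
#' Training mode uses per-sample batch-norm statistics (and updates the
#' running averages); evaluation mode uses the stored running statistics,
#' making forward passes deterministic.
#' @param model model environment
#' @param training logical
#' @export
set_train_mode <- function(model, training = TRUE) {
  model$training <- isTRUE(training)
  invisible(model)
}

#' Training configuration
#'
#' @param phase one of `"pretrain"`, `"multitask"`, `"finetune_disp"`,
#'   `"finetune_seg"`
#' @param variant encoder variant
#' @param epochs,batch_size loop sizes
#' @param lr_schedule `"one_cycle"` (max 1e-3) or `"constant"` (1e-4)
#' @param max_lr peak learning rate
#' @param weight_decay decoupled weight decay (AdamW)
#' @param betas Adam moment coefficients
#' @param crop `c(width, height)` of random training crops (divisible by 32),
#'   or NULL to train on full frames
#' @param vflip_prob probability of a random vertical flip
#' @param norm_mean,norm_std per-channel color-normalization statistics
#' @param seed master seed driving augmentation and data order
#' @param weights a [loss_weights()] list
#' @param width_scale model capacity multiplier (forwarded to the factory)
#' @param log_path optional JSON-lines file receiving per-epoch records
#' @return a `train_config` list
#' @export
train_config <- function(phase = c("pretrain", "multitask", "finetune_disp",
                                   "finetune_seg"),
                         variant = "lightweight", epochs = 1L, batch_size = 4L,
                         lr_schedule = c("one_cycle", "constant"),
                         max_lr = if (match.arg(lr_schedule) == "one_cycle") 1e-3 else 1e-4,
                         weight_decay = 1e-4, betas = c(0.9, 0.999),
                         crop = NULL, vflip_prob = 0.5,
                         norm_mean = c(0.485, 0.456, 0.406),
                         norm_std = c(0.229, 0.224, 0.225),
                         seed = 42L, weights = loss_weights(),
                         width_scale = 1, log_path = NULL) {
  phase <- match.arg(phase)
  lr_schedule <- match.arg(lr_schedule)
  if (!is.null(crop) && any(crop %% 32 != 0))
    stop("crop dimensions must be divisible by 32")
  stopifnot(vflip_prob >= 0, vflip_prob <= 1)
  structure(list(phase = phase, variant = variant, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_schedule = lr_schedule,
                 max_lr = max_lr, weight_decay = weight_decay, betas = betas,
                 crop = crop, vflip_prob = vflip_prob, norm_mean = norm_mean,
                 norm_std = norm_std, seed = as.integer(seed), weights = weights,
                 width_scale = width_scale, log_path = log_path),
            class = "train_config")
}

#' Color-normalize an image with per-channel statistics
#' @param image H x W x 3 array; mean,std length-3 vectors
#' @return normalized array
#' @export
normalize_image <- function(image, mean = c(0.485, 0.456, 0.406),
                            std = c(0.229, 0.224, 0.225)) {
  for (c in 1:3) image[, , c] <- (image[, , c] - mean[c]) / std[c]
  image
}

flip_rows <- function(a) {
  if (is.null(a)) return(NULL)
  d <- dim(a)
  if (length(d) == 3L) a[rev(seq_len(d[1])), , , drop = FALSE]
  else a[rev(seq_len(d[1])), , drop = FALSE]
}

#' Augment a stereo sample for training
#'
#' Applies one random crop (identical window for both views and all
#' per-pixel channels — horizontal cropping leaves disparity values intact),
#' a random vertical flip (rows stay aligned, so rectification is
#' preserved), and color normalization of the two views.
#' @param sample a [stereo_sample()]
#' @param config a [train_config()]
#' @param seed integer seed making the augmentation reproducible
#' @return an augmented `stereo_sample` (views normalized)
#' @export
augment_sample <- function(sample, config, seed) {
  with_local_seed(seed, {
    d <- dim(sample$left)
    out <- sample
    if (!is.null(config$crop)) {
      cw <- config$crop[1]; ch <- config$crop[2]
      if (cw > d[2] || ch > d[1])
        stop(sprintf("crop %dx%d larger than the %dx%d sample", cw, ch, d[2], d[1]))
      x0 <- sample.int(d[2] - cw + 1L, 1L) - 1L
      y0 <- sample.int(d[1] - ch + 1L, 1L) - 1L
      rows <- y0 + seq_len(ch); cols <- x0 + seq_len(cw)
      out$left <- out$left[rows, cols, , drop = FALSE]
      out$right <- out$right[rows, cols, , drop = FALSE]
      for (nm in c("disparity", "valid", "mask"))
        if (!is.null(out[[nm]])) out[[nm]] <- out[[nm]][rows, cols, drop = FALSE]
    }
    if (stats::runif(1) < config$vflip_prob) {
      out$left <- flip_rows(out$left)
      out$right <- flip_rows(out$right)
      for (nm in c("disparity", "valid", "mask"))
        if (!is.null(out[[nm]])) out[[nm]] <- flip_rows(out[[nm]])
    }
    out$left <- normalize_image(out$left, config$norm_mean, config$norm_std)
    out$right <- normalize_image(out$right, config$norm_mean, config$norm_std)
    out
  })
}

# ---- optimizer -------------------------------------------------------------

#' Create an AdamW optimizer over a named parameter list
#' @param params named list of `ag_param` nodes
#' @param betas moment coefficients; weight_decay decoupled decay; eps stabilizer
#' @return optimizer environment with `$step(lr)`
#' @keywords internal
adamw <- function(params, betas = c(0.9, 0.999), weight_decay = 1e-4, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$m <- lapply(params, function(p) p$value * 0)
  opt$v <- lapply(params, function(p) p$value * 0)
  opt$t <- 0L
  opt$step <- function(lr) {
    opt$t <- opt$t + 1L
    b1 <- betas[1]; b2 <- betas[2]
    bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
    for (i in seq_along(opt$params)) {
      p <- opt$params[[i]]
      g <- p$grad
      if (is.null(g)) next
      opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
      opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
      mhat <- opt$m[[i]] / bc1
      vhat <- opt$v[[i]] / bc2
      p$value <- p$value - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p$value)
    }
    ag_zero_grad(opt$params)
    invisible(NULL)
  }
  opt
}

# learning rate at step t (1-based) of total n
lr_at <- function(config, t, n) {
  if (config$lr_schedule == "constant") return(config$max_lr)
  warm <- max(1, round(0.3 * n))
  if (t <= warm) config$max_lr * t / warm
  else config$max_lr * (1 + cos(pi * (t - warm) / max(1, n - warm))) / 2
}

phase_needs <- function(phase) {
  switch(phase,
         pretrain = "disparity ground truth",
         finetune_disp = "disparity ground truth",
         finetune_seg = "instrument masks",
         multitask = "rectified pairs and instrument masks")
}

check_phase_dataset <- function(phase, dataset) {
  ok <- switch(phase,
    pretrain = ,
    finetune_disp = all(vapply(dataset, function(s) !is.null(s$disparity), logical(1))),
    finetune_seg = all(vapply(dataset, function(s) !is.null(s$mask), logical(1))),
    multitask = all(vapply(dataset, function(s) !is.null(s$mask), logical(1))))
  if (!ok)
    stop(sprintf("phase '%s' requires %s for every sample", phase, phase_needs(phase)))
}

# loss of one (already augmented) sample under the given phase
phase_loss <- function(model, sample, config) {
  w <- config$weights
  if (config$phase %in% c("pretrain", "finetune_disp")) {
    pyr <- predict_disparity(model, sample$left, sample$right)
    return(disparity_supervised_loss(pyr, sample$disparity, sample$valid,
                                     w$max_disparity))
  }
  if (config$phase == "finetune_seg") {
    seg <- predict_mask(model, sample$left)
    return(segmentation_loss(sample$mask, seg$probability, w))
  }
  # multitask: segmentation fully supervised, disparity self-supervised at S1
  lp <- extract_pyramid(model, sample$left)
  rp <- extract_pyramid(model, sample$right)
  pyr <- predict_disparity_from_pyramids(model, lp, rp, sample$left)
  seg <- decode_mask(model, lp)
  ss <- self_supervised_disparity_loss(sample$left, sample$right,
                                       pyr$disparity[[1L]], w)
  sl <- segmentation_loss(sample$mask, seg$probability, w)
  multitask_loss(ss, sl, w$alpha_mt)
}

trainable_params <- function(model, phase) {
  # single-task fine-tuning leaves the unused head entirely untouched
  layers <- model$layers
  if (phase %in% c("pretrain", "finetune_disp")) layers$segmentation <- NULL
  if (phase == "finetune_seg") layers$disparity <- NULL
  collect_params(layers)
}

#' Run one training phase
#'
#' Pretrain supervises the disparity pyramid at every scale (the
#' segmentation head may be absent); multitask combines S1-only
#' self-supervised disparity with fully supervised segmentation; the
#' fine-tuning phases optimize a single task and leave the other head's
#' weights untouched.  Per-epoch records go to `config$log_path` as JSON
#' lines when set.
#'
#' @param model a model from [model_factory()]
#' @param dataset list of [stereo_sample()]s supplying what the phase needs
#' @param config a [train_config()]
#' @return list with the trained `model` and a data frame `log`
#' @export
run_phase <- function(model, dataset, config) {
  check_phase_dataset(config$phase, dataset)
  if (config$phase != "finetune_seg" && !("disparity" %in% model$heads))
    stop(sprintf("phase '%s' needs a disparity head", config$phase))
  if (config$phase %in% c("multitask", "finetune_seg") &&
      !("segmentation" %in% model$heads))
    stop(sprintf("phase '%s' needs a segmentation head", config$phase))
  params <- trainable_params(model, config$phase)
  opt <- adamw(params, config$betas, config$weight_decay)
  n <- length(dataset)
  bs <- min(config$batch_size, n)
  steps_per_epoch <- n %/% bs
  total_steps <- config$epochs * steps_per_epoch
  set_train_mode(model, TRUE)
  log <- vector("list", config$epochs)
  step <- 0L
  losses_all <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    ord <- with_local_seed(config$seed + ep, sample.int(n))
    ep_losses <- numeric(steps_per_epoch)
    for (b in seq_len(steps_per_epoch)) {
      step <- step + 1L
      idx <- ord[((b - 1L) * bs + 1L):(b * bs)]
      lr <- lr_at(config, step, total_steps)
      batch_loss <- 0
      for (j in idx) {
        s <- augment_sample(dataset[[j]], config,
                            seed = config$seed * 1000L + step * 100L + j)
        ag_with_tape({
          loss <- phase_loss(model, s, config)
          if (is_ag(loss)) {
            ag_backward(loss, seed = 1 / length(idx))  # mean over the batch
            batch_loss <- batch_loss + ag_value(loss)
          } else batch_loss <- batch_loss + loss
        })
      }
      opt$step(lr)
      ep_losses[b] <- batch_loss / length(idx)
    }
    rec <- list(epoch = ep, phase = config$phase, mean_loss = mean(ep_losses),
                lr = lr_at(config, step, total_steps))
    log[[ep]] <- rec
    losses_all <- c(losses_all, ep_losses)
    if (!is.null(config$log_path))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
          file = config$log_path, append = TRUE, sep = "")
  }
  set_train_mode(model, FALSE)
  list(model = model,
       log = do.call(rbind, lapply(log, as.data.frame)),
       step_losses = losses_all)
}
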