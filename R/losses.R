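# Training objectives: supervised multi-scale disparity loss, segmentation
# loss (weighted BCE + soft dice), self-supervised stereo loss (photometric +
# SSIM + edge-aware smoothness) and the multi-task combination.  Every
# function accepts plain arrays (returning a number) or autodiff nodes
# (returning a tracked scalar), so the same code computes metrics and drives
# training.

#' Loss coefficients and constants
#'
#' Defaults are the operating values of the method: `alpha_mt = 0.2` weights
#' disparity against segmentation in the multi-task loss; `alpha_ss = 0.9`
#' and `beta_ss = 0.7` mix photometric/SSIM/smoothness terms;
#' `beta_wbce = (1 - 0.15)/0.15` rebalances classes given ~15% average tool
#' coverage; `dice_eps = 1e-5` stabilizes the dice ratio; SSIM constants
#' `c1 = 0.01^2`, `c2 = 0.03^2` with an 11x11 window.
#' @param alpha_mt,alpha_ss,beta_ss mixing coefficients in `[0, 1]`
#' @param beta_wbce positive foreground weight of the weighted BCE
#' @param dice_eps positive stabilizer of the soft dice loss
#' @param max_disparity disparity search range in pixels
#' @param ssim_c1,ssim_c2,ssim_window SSIM constants and window size
#' @return a `loss_weights` list
#' @export
loss_weights <- function(alpha_mt = 0.2, alpha_ss = 0.9, beta_ss = 0.7,
                         beta_wbce = (1 - 0.15) / 0.15, dice_eps = 1e-5,
                         max_disparity = 320, ssim_c1 = 0.01^2, ssim_c2 = 0.03^2,
                         ssim_window = 11L) {
  stopifnot(alpha_mt >= 0, alpha_mt <= 1, alpha_ss >= 0, alpha_ss <= 1,
            beta_ss >= 0, beta_ss <= 1, beta_wbce > 0, dice_eps > 0)
  structure(list(alpha_mt = alpha_mt, alpha_ss = alpha_ss, beta_ss = beta_ss,
                 beta_wbce = beta_wbce, dice_eps = dice_eps,
                 max_disparity = max_disparity, ssim_c1 = ssim_c1,
                 ssim_c2 = ssim_c2, ssim_window = as.integer(ssim_window)),
            class = "loss_weights")
}

#' Supervised multi-scale disparity loss
#'
#' Each scale's prediction is bilinearly up-sampled to full resolution and
#' its values multiplied by the resolution ratio ("up-sample and up-scale"),
#' then the smooth-L1 error against the ground truth is averaged over valid
#' pixels; the final loss is the mean across scales.  Pixels invalid in
#' `valid` or with ground truth above `max_disparity` contribute nothing.
#'
#' @param pred a `disparity_pyramid` (or plain list `disparity`), or a single
#'   full-resolution map
#' @param gt H x W ground-truth disparity at full resolution
#' @param valid H x W logical validity mask (NULL means all valid)
#' @param max_disparity ground truth above this is ignored
#' @param scales which pyramid entries to supervise (default all present)
#' @return scalar loss (0, with a warning, if no pixel is valid)
#' @export
disparity_supervised_loss <- function(pred, gt, valid = NULL, max_disparity = 320,
                                      scales = NULL) {
  preds <- if (inherits(pred, "disparity_pyramid")) pred$disparity
  else if (is.list(pred)) pred else list(pred)
  if (!is.null(scales)) preds <- preds[scales]
  preds <- preds[!vapply(preds, is.null, logical(1))]
  if (is.null(valid)) valid <- matrix(TRUE, nrow(gt), ncol(gt))
  mask <- valid & gt <= max_disparity
  if (!any(mask)) {
    warning("no valid pixels; supervised disparity loss defined as 0")
    return(0)
  }
  H <- nrow(gt)
  total <- NULL
  W <- ncol(gt)
  for (p in preds) {
    v <- ag_value(p)
    ratio <- H / dim(v)[1]
    up <- if (ratio > 1) ag_scale(ag_resize_bilinear(p, H, W), ratio) else p
    term <- ag_masked_mean(smooth_l1(ag_sub(up, gt)), mask)
    total <- if (is.null(total)) term else ag_add(total, term)
  }
  ag_scale(total, 1 / length(preds))
}

#' Weighted binary cross-entropy
#'
#' Per-pixel `-(beta * s * log(s_hat) + (1 - s) * log(1 - s_hat))`, averaged
#' over pixels; predictions are clipped to `[1e-7, 1 - 1e-7]` before the
#' logarithms.  `beta > 1` up-weights the (rarer) foreground class.
#' @param s H x W binary reference mask (logical or 0/1)
#' @param s_hat H x W predicted probabilities
#' @param beta positive foreground weight
#' @return scalar loss
#' @export
wbce <- function(s, s_hat, beta = (1 - 0.15) / 0.15) {
  if (beta <= 0) stop("beta must be positive")
  sv <- ag_value(s) * 1
  p <- ag_clip(s_hat, 1e-7, 1 - 1e-7)
  term <- ag_add(ag_scale(ag_mul(sv, ag_log(p)), beta),
                 ag_mul(1 - sv, ag_log(ag_sub(1, p))))
  ag_scale(ag_mean(term), -1)
}

#' Soft dice loss
#'
#' `1 - (2 * sum(s * s_hat) + eps) / (sum(s) + sum(s_hat) + eps)`; the
#' epsilon makes two empty masks score a perfect 0.
#' @inheritParams wbce
#' @param eps positive stabilizer
#' @return scalar loss in `[0, 1]`
#' @export
soft_dice_loss <- function(s, s_hat, eps = 1e-5) {
  sv <- ag_value(s) * 1
  num <- ag_addc(ag_scale(ag_sum(ag_mul(sv, s_hat)), 2), eps)
  den <- ag_addc(ag_add(sum(sv), ag_sum(s_hat)), eps)
  ag_sub(1, ag_div(num, den))
}

#' Combined segmentation loss: equal-weight WBCE + soft dice
#' @inheritParams wbce
#' @param weights a [loss_weights()] list
#' @return scalar loss
#' @export
segmentation_loss <- function(s, s_hat, weights = loss_weights()) {
  ag_add(ag_scale(wbce(s, s_hat, weights$beta_wbce), 0.5),
         ag_scale(soft_dice_loss(s, s_hat, weights$dice_eps), 0.5))
}

#' Structural-similarity loss
#'
#' SSIM computed per channel on uniform `window x window` patches (valid
#' region), averaged into a mean similarity, returned as
#' `(1 - SSIM_m) / 2`, which lies in `[0, 1]`.
#' @param I,I_prime H x W x 3 images in `[0, 1]`
#' @param weights a [loss_weights()] list (window and stability constants)
#' @return scalar loss
#' @export
ssim_loss <- function(I, I_prime, weights = loss_weights()) {
  k <- weights$ssim_window
  d <- dim(ag_value(I))
  if (d[1] < k || d[2] < k)
    stop(sprintf("SSIM window %d exceeds the %dx%d image", k, d[1], d[2]))
  c1 <- weights$ssim_c1; c2 <- weights$ssim_c2
  mu_x <- ag_boxmean(I, k); mu_y <- ag_boxmean(I_prime, k)
  mu_x2 <- ag_square(mu_x); mu_y2 <- ag_square(mu_y)
  mu_xy <- ag_mul(mu_x, mu_y)
  sig_x <- ag_sub(ag_boxmean(ag_square(I), k), mu_x2)
  sig_y <- ag_sub(ag_boxmean(ag_square(I_prime), k), mu_y2)
  sig_xy <- ag_sub(ag_boxmean(ag_mul(I, I_prime), k), mu_xy)
  num <- ag_mul(ag_addc(ag_scale(mu_xy, 2), c1), ag_addc(ag_scale(sig_xy, 2), c2))
  den <- ag_mul(ag_addc(ag_add(mu_x2, mu_y2), c1), ag_addc(ag_add(sig_x, sig_y), c2))
  ssim_m <- ag_mean(ag_div(num, den))
  ag_scale(ag_sub(1, ssim_m), 0.5)
}

#' Photometric reconstruction loss
#'
#' Mean smooth-L1 difference over all pixels and channels; occluded regions
#' are not excluded.
#' @param I_left left image; I_left_warped right image warped to the left view
#' @return scalar loss
#' @export
photometric_loss <- function(I_left, I_left_warped) {
  ag_mean(smooth_l1(ag_sub(I_left, I_left_warped)))
}

#' Edge-aware disparity smoothness loss
#'
#' Penalizes disparity gradients where the image has none:
#' `mean |dx(d/320)| exp(-||dx I||) + mean |dy(d/320)| exp(-||dy I||)`,
#' with `||.||` the mean of absolute channel gradients and forward
#' differences throughout.  The disparity is normalized by the search range
#' so the term shares the scale of the photometric losses.
#' @param I_left H x W x 3 image; disparity H x W map in pixels
#' @param max_disparity normalization constant (pixels)
#' @return scalar loss
#' @export
smoothness_loss <- function(I_left, disparity, max_disparity = 320) {
  dn <- ag_scale(disparity, 1 / max_disparity)
  Iv <- ag_value(I_left)
  grad_w <- function(diff_fun) {
    g <- 0
    for (c in 1:3) g <- g + abs(diff_fun(Iv[, , c]))
    exp(-g / 3)
  }
  wx <- grad_w(function(m) m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])
  wy <- grad_w(function(m) m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
  tx <- ag_mean(ag_mul(ag_abs(ag_fdx(dn)), wx))
  ty <- ag_mean(ag_mul(ag_abs(ag_fdy(dn)), wy))
  ag_add(tx, ty)
}

#' Self-supervised stereo loss at full resolution
#'
#' Warps the right view to the left with the predicted S1 disparity and
#' combines photometric, SSIM and smoothness terms:
#' `beta_ss * (alpha_ss * L_ph + (1 - alpha_ss) * L_ssim) +
#'  (1 - beta_ss) * L_smooth`.
#' @param I_left,I_right rectified pair
#' @param disparity_s1 full-resolution predicted disparity
#' @param weights a [loss_weights()] list
#' @return scalar loss
#' @export
self_supervised_disparity_loss <- function(I_left, I_right, disparity_s1,
                                           weights = loss_weights()) {
  warped <- warp_right_to_left(I_right, disparity_s1)
  ph <- photometric_loss(I_left, warped)
  ss <- ssim_loss(I_left, warped, weights)
  sm <- smoothness_loss(I_left, disparity_s1, weights$max_disparity)
  ag_add(ag_scale(ag_add(ag_scale(ph, weights$alpha_ss),
                         ag_scale(ss, 1 - weights$alpha_ss)), weights$beta_ss),
         ag_scale(sm, 1 - weights$beta_ss))
}

#' Multi-task combination of disparity and segmentation losses
#' @param ss_disp_value self-supervised disparity loss value (or node)
#' @param seg_value segmentation loss value (or node)
#' @param alpha_mt disparity weight in `[0, 1]`
#' @return `alpha_mt * ss_disp + (1 - alpha_mt) * seg`
#' @export
multitask_loss <- function(ss_disp_value, seg_value, alpha_mt = 0.2) {
  ag_add(ag_scale(ss_disp_value, alpha_mt), ag_scale(seg_value, 1 - alpha_mt))
}
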