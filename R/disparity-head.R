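# Cascade cost-volume disparity head.
#
# From the coarsest scale S6 down to S2, each stage pre-aligns the right
# features with the up-sampled/up-scaled disparity of the previous scale,
# builds a shallow +/-2 cost volume, and regresses a residual correction.
# At full resolution S1 no cost volume is built (tolerating ~2 px of vertical
# rectification error); a 2-D hourglass refines the up-scaled S2 output as a
# residual connection.  All convolutions except the disparity-regressing ones
# are followed by batch norm and LeakyReLU(0.1).

TOWER_WIDTHS <- c(128L, 128L, 96L, 64L, 32L)

# 3x3 learned up-scaling conv on a 1-channel disparity map, initialized to
# the exact x2 identity (center tap 2) so early training starts from plain
# bilinear doubling.
layer_upconv <- function() {
  W <- matrix(0, 9L, 1L)
  W[5L, 1L] <- 2
  list(type = "conv", W = ag_param(W), b = ag_param(0), k = 3L, stride = 1L,
       pad = 1L, cin = 1L, cout = 1L)
}

build_refine_tower <- function(cin, widths) {
  tower <- list()
  for (i in seq_along(widths)) {
    tower[[i]] <- list(conv = layer_conv(cin, widths[i]), bn = layer_bn(widths[i]))
    cin <- widths[i]
  }
  # the disparity-regressing conv starts at zero so the stage initially
  # passes the up-scaled coarser estimate through unchanged (residual = 0)
  tower$out <- layer_conv(cin, 1L, bias = TRUE, init_sd = 0)
  tower
}

fwd_refine_tower <- function(tower, x, training) {
  for (i in seq_len(length(tower) - 1L))
    x <- fwd_cbl(tower[[i]]$conv, tower[[i]]$bn, x, training)
  fwd_conv(tower$out, x)
}

build_disparity_head <- function(feat_widths, width_scale = 1, max_disparity = 320) {
  tw <- pmax(2L, as.integer(round(TOWER_WIDTHS * width_scale)))
  n_planes_s6 <- as.integer(max_disparity / 32) + 1L
  stages <- list()
  for (i in 2:6) {
    d_planes <- if (i == 6L) n_planes_s6 else 5L
    stages[[paste0("s", i)]] <- list(
      upconv = if (i < 6L) layer_upconv() else NULL,
      tower = build_refine_tower(d_planes + feat_widths[i - 1L], tw)
    )
  }
  # hourglass convs carry biases and no batch norm: per-sample batch
  # statistics would cancel the (locally near-constant) disparity channel
  # and amplify its sub-pixel ripples, destabilizing the residual
  hg_w <- pmax(2L, as.integer(round(c(32L, 64L) * width_scale)))
  hourglass <- list(
    down1 = list(conv = layer_conv(4L, hg_w[1], stride = 2L, bias = TRUE)),
    down2 = list(conv = layer_conv(hg_w[1], hg_w[2], stride = 2L, bias = TRUE)),
    up1 = list(convT = layer_convT(hg_w[2], hg_w[1], bias = TRUE)),
    mix1 = list(conv = layer_conv(2L * hg_w[1], hg_w[1], bias = TRUE)),
    up2 = list(convT = layer_convT(hg_w[1], hg_w[1], bias = TRUE)),
    out = layer_conv(hg_w[1], 1L, bias = TRUE, init_sd = 0)  # zero-init residual
  )
  list(stages = stages, upconv_s1 = layer_upconv(), hourglass = hourglass,
       max_disparity = max_disparity, n_planes_s6 = n_planes_s6)
}

as_hw <- function(x) {
  # drop a trailing singleton channel dim of an array/node value
  v <- ag_value(x)
  if (length(dim(v)) == 3L && dim(v)[3] == 1L) {
    d <- dim(v)[1:2]
    ag_op(array(v, d), list(x), function(g) list(array(g, c(d, 1L))))
  } else x
}

as_hw1 <- function(x) {
  v <- ag_value(x)
  if (length(dim(v)) == 2L) {
    d <- dim(v)
    ag_op(array(v, c(d, 1L)), list(x), function(g) list(array(g, d)))
  } else x
}

#' Estimate disparity at one pyramid scale
#'
#' For scales 2..5: bilinearly up-sample the previous (coarser) disparity,
#' refine and double it with a learned 3x3 conv, warp the right features by
#' it, build the bidirectional +/-2 cost volume against the left features,
#' and add the residual regressed from `[cost volume, left features]` by the
#' refinement tower.  At scale 6 a unidirectional volume over offsets
#' `0..max_disparity/32` is built directly and the tower output is the
#' disparity itself (no identity connection).
#'
#' @param model model from [model_factory()] with a disparity head
#' @param scale integer in 2..6
#' @param left_feat,right_feat feature maps at this scale
#' @param disparity_prev disparity at scale `scale + 1` (required for scales
#'   2..5, must be absent at scale 6)
#' @return H_i x W_i disparity map in this scale's pixel units
#' @export
estimate_scale <- function(model, scale, left_feat, right_feat, disparity_prev = NULL) {
  head <- model$layers$disparity
  if (is.null(head)) stop("model has no disparity head")
  training <- model$training
  st <- head$stages[[paste0("s", scale)]]
  if (scale == 6L) {
    if (!is.null(disparity_prev))
      stop("scale 6 is the cascade root; disparity_prev must be absent")
    cv <- build_cost_volume(left_feat, right_feat, 0:(head$n_planes_s6 - 1L))
    x <- ag_concat_c(list(cv, left_feat))
    return(as_hw(fwd_refine_tower(st$tower, x, training)))
  }
  if (is.null(disparity_prev))
    stop(sprintf("scale %d needs the disparity of scale %d", scale, scale + 1L))
  up <- ag_upsample_x2(disparity_prev)
  refined <- as_hw(fwd_conv(st$upconv, as_hw1(up)))
  aligned <- warp_right_to_left(right_feat, refined)
  cv <- build_cost_volume(left_feat, aligned, -2:2)
  x <- ag_concat_c(list(cv, left_feat))
  residual <- as_hw(fwd_refine_tower(st$tower, x, training))
  ag_add(refined, residual)
}

#' Refine the half-resolution disparity to full resolution
#'
#' Up-scales the S2 disparity with a learned conv and adds the residual of a
#' small 2-D hourglass fed with the up-scaled disparity and the left image.
#' No cost volume is built at S1.
#'
#' @param model model with a disparity head
#' @param disparity_s2 H/2 x W/2 disparity map
#' @param left_image H x W x 3 left view
#' @return H x W disparity map (the deployment output)
#' @export
refine_full_res <- function(model, disparity_s2, left_image) {
  head <- model$layers$disparity
  if (is.null(head)) stop("model has no disparity head")
  training <- model$training
  d_img <- dim(ag_value(left_image))
  d_s2 <- dim(ag_value(disparity_s2))
  if (!identical(as.integer(d_s2[1:2] * 2L), as.integer(d_img[1:2])))
    stop("disparity_s2 must have half the spatial size of left_image")
  up <- as_hw(fwd_conv(head$upconv_s1, as_hw1(ag_upsample_x2(disparity_s2))))
  hg <- head$hourglass
  # the disparity channel enters normalized by the search range so it shares
  # the scale of the image channels
  x0 <- ag_concat_c(list(as_hw1(ag_scale(up, 1 / head$max_disparity)), left_image))
  d1 <- ag_leaky_relu(fwd_conv(hg$down1$conv, x0), 0.1)
  d2 <- ag_leaky_relu(fwd_conv(hg$down2$conv, d1), 0.1)
  u1 <- ag_leaky_relu(fwd_convT(hg$up1$convT, d2), 0.1)
  m1 <- ag_leaky_relu(fwd_conv(hg$mix1$conv, ag_concat_c(list(u1, d1))), 0.1)
  u2 <- ag_leaky_relu(fwd_convT(hg$up2$convT, m1), 0.1)
  residual <- as_hw(fwd_conv(hg$out, u2))
  ag_add(up, residual)
}

#' Predict the full disparity pyramid for a rectified stereo pair
#'
#' Runs the shared encoder on both views, cascades the matching module from
#' S6 down to S2, and refines to full resolution.  The S1 entry is the
#' deployment output, in pixels at input resolution.
#'
#' @param model model with a disparity head
#' @param left,right H x W x 3 rectified, normalized views
#' @return a `disparity_pyramid`: list `disparity` indexed 1..6 (scale i has
#'   spatial size `H/2^(i-1)` and pixel units at that resolution)
#' @export
predict_disparity <- function(model, left, right) {
  lp <- extract_pyramid(model, left)
  rp <- extract_pyramid(model, right)
  predict_disparity_from_pyramids(model, lp, rp, left)
}

#' @rdname predict_disparity
#' @param left_pyramid,right_pyramid precomputed [extract_pyramid()] outputs
#' @param left_image the left view (consumed by the S1 hourglass)
#' @export
predict_disparity_from_pyramids <- function(model, left_pyramid, right_pyramid,
                                            left_image) {
  if (!identical(left_pyramid$variant, right_pyramid$variant))
    stop("left and right pyramids come from different encoder variants")
  if (!identical(left_pyramid$variant, model$variant))
    stop("pyramid variant does not match the model")
  lf <- left_pyramid$features; rf <- right_pyramid$features
  disp <- vector("list", 6L)
  disp[[6L]] <- estimate_scale(model, 6L, lf$s6, rf$s6)
  for (i in 5:2)
    disp[[i]] <- estimate_scale(model, i, lf[[paste0("s", i)]], rf[[paste0("s", i)]],
                                disp[[i + 1L]])
  disp[[1L]] <- refine_full_res(model, disp[[2L]], left_image)
  structure(list(disparity = disp), class = "disparity_pyramid")
}
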