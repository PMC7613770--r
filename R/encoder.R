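# Shared feature encoders: a lightweight 5-block pyramidal encoder and a
# standard ResNet34 feature extractor.  Both emit feature maps at scales
# S2..S6 (resolutions /2 .. /32) which feed the disparity and segmentation
# heads.  Convolutions feeding batch norm carry no bias (it is redundant
# with the batch-norm shift).

LIGHTWEIGHT_WIDTHS <- c(16L, 32L, 64L, 96L, 128L)
RESNET34_WIDTHS <- c(64L, 64L, 128L, 256L, 512L)

#' Per-scale channel widths of an encoder variant
#' @param variant `"lightweight"` or `"resnet34"`
#' @param width_scale multiplier on the lightweight widths (capacity knob for
#'   small-scale experiments; ignored for resnet34)
#' @return integer vector of channel counts for scales 2..6
#' @export
encoder_widths <- function(variant = c("lightweight", "resnet34"), width_scale = 1) {
  variant <- match.arg(variant)
  if (variant == "lightweight") pmax(2L, as.integer(round(LIGHTWEIGHT_WIDTHS * width_scale)))
  else RESNET34_WIDTHS
}

build_lightweight_encoder <- function(widths = LIGHTWEIGHT_WIDTHS) {
  cin <- 3L
  blocks <- list()
  for (i in seq_along(widths)) {
    blocks[[i]] <- list(
      conv1 = layer_conv(cin, widths[i], k = 3L, stride = 2L, pad = 1L),
      bn1 = layer_bn(widths[i]),
      conv2 = layer_conv(widths[i], widths[i], k = 3L, stride = 1L, pad = 1L),
      bn2 = layer_bn(widths[i])
    )
    cin <- widths[i]
  }
  blocks
}

fwd_lightweight <- function(blocks, x, training) {
  feats <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    x <- fwd_cbl(b$conv1, b$bn1, x, training)
    x <- fwd_cbl(b$conv2, b$bn2, x, training)
    feats[[i]] <- x
  }
  feats
}

basic_block <- function(cin, cout, stride = 1L) {
  list(
    conv1 = layer_conv(cin, cout, k = 3L, stride = stride, pad = 1L),
    bn1 = layer_bn(cout),
    conv2 = layer_conv(cout, cout, k = 3L, stride = 1L, pad = 1L),
    bn2 = layer_bn(cout),
    down = if (stride != 1L || cin != cout)
      list(conv = layer_conv(cin, cout, k = 1L, stride = stride, pad = 0L),
           bn = layer_bn(cout))
    else NULL
  )
}

fwd_basic_block <- function(b, x, training) {
  y <- ag_relu(fwd_bn(b$bn1, fwd_conv(b$conv1, x), training))
  y <- fwd_bn(b$bn2, fwd_conv(b$conv2, y), training)
  sc <- if (is.null(b$down)) x else fwd_bn(b$down$bn, fwd_conv(b$down$conv, x), training)
  ag_relu(ag_add(y, sc))
}

build_resnet34_encoder <- function() {
  stage <- function(cin, cout, n, stride)
    c(list(basic_block(cin, cout, stride)),
      lapply(seq_len(n - 1L), function(i) basic_block(cout, cout, 1L)))
  list(
    stem_conv = layer_conv(3L, 64L, k = 7L, stride = 2L, pad = 3L),
    stem_bn = layer_bn(64L),
    layer1 = stage(64L, 64L, 3L, 1L),
    layer2 = stage(64L, 128L, 4L, 2L),
    layer3 = stage(128L, 256L, 6L, 2L),
    layer4 = stage(256L, 512L, 3L, 2L)
  )
}

fwd_resnet34 <- function(layers, x, training) {
  s2 <- ag_relu(fwd_bn(layers$stem_bn, fwd_conv(layers$stem_conv, x), training))
  x <- ag_maxpool(s2, k = 3L, stride = 2L, pad = 1L)
  run_stage <- function(st, x) { for (b in st) x <- fwd_basic_block(b, x, training); x }
  s3 <- run_stage(layers$layer1, x)
  s4 <- run_stage(layers$layer2, s3)
  s5 <- run_stage(layers$layer3, s4)
  s6 <- run_stage(layers$layer4, s5)
  list(s2, s3, s4, s5, s6)
}

#' Extract the five-scale feature pyramid from an image
#'
#' @param model a model from [model_factory()]
#' @param image H x W x 3 array, H and W divisible by 32, already
#'   color-normalized (normalization is the caller's job)
#' @return a `feature_pyramid`: list with `features` (named `s2`..`s6`) and
#'   the `variant` tag.  Scale `i` has spatial size `H/2^(i-1)` and the
#'   variant's channel width.
#' @export
extract_pyramid <- function(model, image) {
  d <- dim(ag_value(image))
  if (length(d) != 3L || d[3] != 3L) stop("image must be H x W x 3")
  if (d[1] %% 32 != 0) stop(sprintf("height %d is not divisible by 32", d[1]))
  if (d[2] %% 32 != 0) stop(sprintf("width %d is not divisible by 32", d[2]))
  feats <- if (model$variant == "resnet34")
    fwd_resnet34(model$layers$encoder, image, model$training)
  else
    fwd_lightweight(model$layers$encoder, image, model$training)
  names(feats) <- paste0("s", 2:6)
  structure(list(features = feats, variant = model$variant),
            class = "feature_pyramid")
}

#' Count trainable parameters of a model scope
#'
#' @param variant encoder variant, or an existing model environment
#' @param scope one of `"encoder"`, `"disparity_head"`, `"segmentation_head"`,
#'   `"full_multitask"`
#' @param freeze_bn when TRUE, batch-norm affine parameters are excluded from
#'   the count (the freezing contract removes exactly 2 scalars per channel)
#' @return integer number of trainable scalars
#' @export
count_parameters <- function(variant, scope = c("encoder", "disparity_head",
                                                "segmentation_head", "full_multitask"),
                             freeze_bn = FALSE) {
  scope <- match.arg(scope)
  model <- if (is.environment(variant)) variant
  else model_factory(variant, heads = c("disparity", "segmentation"))
  layers <- switch(scope,
    encoder = model$layers$encoder,
    disparity_head = model$layers$disparity,
    segmentation_head = model$layers$segmentation,
    full_multitask = model$layers)
  if (is.null(layers)) stop(sprintf("model has no %s", scope))
  total <- n_params(layers)
  if (freeze_bn) {
    bn <- collect_bn_states(layers)
    # each bn layer holds gamma + beta, one scalar per channel each
    frozen <- sum(vapply(bn, function(s) 2L * length(s$running_mean), integer(1)))
    total <- total - frozen
  }
  as.integer(total)
}
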