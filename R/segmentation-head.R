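# U-Net style segmentation head over the shared feature pyramid.
# The decoder ascends S6 -> S2 using 4x4 stride-2 transposed convolutions
# (so up-sampled maps exactly match the skip-connection sizes), concatenates
# the encoder skip at each scale, and processes with two 3x3 conv/bn/
# LeakyReLU(0.1) stages.  The S2 output is up-sampled once more and convolved
# to a single logit channel at full resolution.

build_segmentation_head <- function(feat_widths) {
  w <- feat_widths          # widths at scales 2..6 (index 1..5)
  stages <- list()
  for (j in 5:2) {          # decode to scale j
    cj <- w[j - 1L]; cprev <- w[j]
    stages[[paste0("s", j)]] <- list(
      up = layer_convT(cprev, cj),
      conv1 = layer_conv(2L * cj, cj), bn1 = layer_bn(cj),
      conv2 = layer_conv(cj, cj), bn2 = layer_bn(cj)
    )
  }
  list(stages = stages,
       up_s1 = layer_convT(w[1L], w[1L]),
       out = layer_conv(w[1L], 1L, bias = TRUE))
}

#' Decode a feature pyramid into full-resolution segmentation logits
#'
#' @param model model from [model_factory()] with a segmentation head
#' @param pyramid a complete [extract_pyramid()] output (scales 2..6)
#' @return a `segmentation_output`: list with `logits`, `probability`
#'   (sigmoid) and `mask` (probability > 0.5), each H x W
#' @export
decode_mask <- function(model, pyramid) {
  head <- model$layers$segmentation
  if (is.null(head)) stop("model has no segmentation head")
  training <- model$training
  f <- pyramid$features
  for (s in paste0("s", 2:6))
    if (is.null(f[[s]])) stop(sprintf("pyramid is missing scale %s", s))
  x <- f$s6
  for (j in 5:2) {
    st <- head$stages[[paste0("s", j)]]
    x <- fwd_convT(st$up, x)
    x <- ag_concat_c(list(x, f[[paste0("s", j)]]))
    x <- fwd_cbl(st$conv1, st$bn1, x, training)
    x <- fwd_cbl(st$conv2, st$bn2, x, training)
  }
  logits <- as_hw(fwd_conv(head$out, fwd_convT(head$up_s1, x)))
  probability <- ag_sigmoid(logits)
  structure(list(logits = logits, probability = probability,
                 mask = binarize(ag_value(probability))),
            class = "segmentation_output")
}

#' Predict an instrument mask from a single (left) image
#' @param model model with a segmentation head
#' @param image H x W x 3 normalized image
#' @return a `segmentation_output`
#' @export
predict_mask <- function(model, image) decode_mask(model, extract_pyramid(model, image))

#' Threshold a probability map into a binary mask
#'
#' Uses a strict greater-than comparison, so ties go to background; the 0.5
#' default is the operating point used for all reported results.
#' @param probability H x W array in `[0, 1]`
#' @param threshold scalar in `[0, 1]`
#' @return H x W logical matrix
#' @export
binarize <- function(probability, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  p <- ag_value(probability)
  m <- p > threshold
  dim(m) <- dim(p)
  m
}
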