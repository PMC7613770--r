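# Shared fixtures: tiny models and a finite-difference gradient checker.

tiny_model <- function(heads = c("disparity", "segmentation"), seed = 7L,
                       width_scale = 0.25) {
  model_factory("lightweight", heads = heads, width_scale = width_scale, seed = seed)
}

# relative max deviation between analytic and central-difference gradients of
# a scalar-valued function of one array input
fd_grad_error <- function(fwd, x0, eps = 1e-5) {
  analytic <- surgstereo:::ag_with_tape({
    xn <- surgstereo:::ag_input(x0)
    loss <- fwd(xn)
    surgstereo:::ag_backward(loss)
    xn$grad
  })
  numeric_grad <- array(0, dim(x0))
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    numeric_grad[i] <- (surgstereo:::ag_value(fwd(xp)) -
                          surgstereo:::ag_value(fwd(xm))) / (2 * eps)
  }
  max(abs(analytic - numeric_grad)) / max(1e-8, max(abs(numeric_grad)))
}

norm01 <- function(img) normalize_image(img, rep(0.5, 3), rep(0.5, 3))

random_image <- function(h, w, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# Brute-force oracles for the warp and cost-volume operators.
brute_force_warp <- function(source, disparity) {
  d <- dim(source)
  out <- array(0, d)
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    xs <- x - disparity[y, x]
    x0 <- floor(xs); w <- xs - x0
    for (c in seq_len(d[3])) {
      v0 <- if (x0 >= 1 && x0 <= d[2]) source[y, x0, c] else 0
      v1 <- if (x0 + 1 >= 1 && x0 + 1 <= d[2]) source[y, x0 + 1, c] else 0
      out[y, x, c] <- (1 - w) * v0 + w * v1
    }
  }
  out
}

brute_force_cost_volume <- function(l, r, offsets) {
  d <- dim(l)
  out <- array(0, c(d[1], d[2], length(offsets)))
  for (k in seq_along(offsets)) for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    xs <- x - offsets[k]
    rv <- if (xs >= 1 && xs <= d[2]) r[y, xs, ] else rep(0, d[3])
    out[y, x, k] <- mean(l[y, x, ] * rv)
  }
  out
}

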