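# Synthetic stereo scenes with exactly known disparity, plus tool-like
# binary masks.  These generators make the whole pipeline testable without
# any external dataset: textures are random but smooth enough for bilinear
# photometric residuals to be well conditioned, and every sample satisfies
# the rectification contract left(x, y) = right(x - d(x, y), y).

MAX_DISPARITY <- 320

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a stereo training sample
#'
#' @param left,right H x W x 3 intensity arrays in `[0, 1]`
#' @param disparity optional H x W non-negative disparity map (pixels)
#' @param valid optional H x W logical validity mask
#' @param mask optional H x W logical instrument mask
#' @return an object of class `stereo_sample`
#' @export
stereo_sample <- function(left, right, disparity = NULL, valid = NULL, mask = NULL) {
  d <- dim(left)
  if (!identical(dim(right), d)) stop("left and right dimensions differ")
  for (nm in c("disparity", "valid", "mask")) {
    a <- get(nm)
    if (!is.null(a) && !identical(dim(a)[1:2], d[1:2]))
      stop(sprintf("%s does not match the image size", nm))
  }
  if (!is.null(disparity)) {
    if (any(disparity < 0)) stop("disparity must be non-negative")
    if (any(disparity > MAX_DISPARITY))
      stop(sprintf("disparity exceeds the %d px search range", MAX_DISPARITY))
  }
  structure(list(left = left, right = right, disparity = disparity,
                 valid = valid, mask = mask),
            class = "stereo_sample")
}

#' @export
print.stereo_sample <- function(x, ...) {
  d <- dim(x$left)
  cat(sprintf("<stereo_sample %dx%d, disparity: %s, mask: %s>\n", d[1], d[2],
              if (is.null(x$disparity)) "absent" else
                sprintf("[%.2f, %.2f] px", min(x$disparity), max(x$disparity)),
              if (is.null(x$mask)) "absent" else
                sprintf("%.1f%% fg", 100 * mean(x$mask))))
  invisible(x)
}

check_divisible_32 <- function(height, width) {
  if (height %% 32 != 0) stop(sprintf("height %d is not divisible by 32", height))
  if (width %% 32 != 0) stop(sprintf("width %d is not divisible by 32", width))
}

# Smoothed uniform-noise texture; pure white noise aliases under sub-pixel
# shifts, so a small Gaussian blur keeps bilinear residuals well conditioned.
random_texture <- function(height, width, sigma = 1.1) {
  k <- 2L * ceiling(2 * sigma) + 1L
  g <- exp(-((seq_len(k) - (k + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  Wk <- matrix(as.vector(outer(g, g)), k * k, 1L)
  out <- array(0, c(height, width, 3L))
  pad <- (k - 1L) %/% 2L
  for (c in 1:3) {
    noise <- array(stats::runif(height * width), c(height, width, 1L))
    out[, , c] <- ag_conv2d(noise, Wk, NULL, k = k, stride = 1L, pad = pad)[, , 1L]
  }
  # renormalize contrast (blur + zero padding compresses the range)
  out <- (out - min(out)) / max(1e-9, max(out) - min(out))
  0.05 + 0.9 * out
}

# Sample an array's columns at real-valued positions `xs` (per-pixel),
# bilinear in x, zero outside.  Thin non-tracked wrapper over the warp op.
sample_columns <- function(a, xs) {
  X <- matrix(rep(seq_len(ncol(xs)), each = nrow(xs)), nrow(xs), ncol(xs))
  warp_right_to_left(a, X - xs)
}

#' Generate a fronto-parallel stereo scene (constant disparity)
#'
#' The simplest verifiable stereo fixture: a random-dot texture shifted
#' horizontally by a constant amount.  The leftmost `ceiling(shift)` columns
#' of the left view have no right-image correspondence and are marked
#' invalid.
#'
#' @param height,width image size, each divisible by 32
#' @param shift constant disparity in pixels, `0 <= shift <= min(320, width/2)`
#'   (larger shifts would leave too few corresponding columns to match)
#' @param seed integer seed; identical arguments give bit-identical samples
#' @return a [stereo_sample()] with dense disparity and validity
#' @export
generate_fronto_scene <- function(height, width, shift, seed) {
  check_divisible_32(height, width)
  lim <- min(MAX_DISPARITY, width / 2)
  if (shift < 0 || shift > lim)
    stop(sprintf("shift %.2f outside the allowed range [0, %.1f]", shift, lim))
  with_local_seed(seed, {
    ext <- as.integer(ceiling(shift)) + 1L
    tex <- random_texture(height, width + ext)
    left <- tex[, seq_len(width), , drop = FALSE]
    # right(u) = texture(u + shift): sample the extended texture, then crop
    xs <- matrix(rep(seq_len(width + ext), each = height), height, width + ext) + shift
    right <- sample_columns(tex, xs)[, seq_len(width), , drop = FALSE]
    disparity <- matrix(shift, height, width)
    valid <- matrix(TRUE, height, width)
    if (shift > 0) valid[, seq_len(as.integer(ceiling(shift)))] <- FALSE
    stereo_sample(left, right, disparity, valid)
  })
}

#' Generate a stereo scene with a smooth, spatially varying disparity field
#'
#' The disparity field is a clipped sum of random 2-D Gaussian bumps over a
#' random base level.  The right view is a random texture; the left view is
#' that texture resampled through the disparity field, so the rectification
#' contract holds by construction.  Validity excludes pixels whose source
#' column falls outside the image and pixels occluded under a forward
#' z-buffer over right-image columns (nearest disparity wins).
#'
#' @param height,width image size, each divisible by 32
#' @param d_min,d_max disparity range, `0 <= d_min < d_max <= 320`
#'   (`d_min == d_max` degenerates to a fronto-parallel scene)
#' @param seed integer seed
#' @return a [stereo_sample()] with dense disparity and validity
#' @export
generate_smooth_scene <- function(height, width, d_min, d_max, seed) {
  check_divisible_32(height, width)
  if (d_min < 0 || d_max > MAX_DISPARITY || d_min > d_max)
    stop(sprintf("disparity range [%.1f, %.1f] outside [0, %d]",
                 d_min, d_max, MAX_DISPARITY))
  with_local_seed(seed, {
    xg <- matrix(rep(seq_len(width), each = height), height, width)
    yg <- matrix(rep(seq_len(height), times = width), height, width)
    disp <- matrix(stats::runif(1, d_min, d_max), height, width)
    if (d_max > d_min) {
      for (b in seq_len(6L)) {
        cx <- stats::runif(1, 1, width); cy <- stats::runif(1, 1, height)
        sx <- stats::runif(1, width / 6, width / 2)
        sy <- stats::runif(1, height / 6, height / 2)
        amp <- stats::runif(1, -1, 1) * (d_max - d_min) / 2
        disp <- disp + amp * exp(-((xg - cx)^2 / (2 * sx^2) +
                                     (yg - cy)^2 / (2 * sy^2)))
      }
      disp <- pmin(pmax(disp, d_min), d_max)
      dim(disp) <- c(height, width)
    }
    right <- random_texture(height, width)
    left <- warp_right_to_left(right, disp)
    src <- xg - disp
    valid <- src >= 1 & src <= width
    # forward z-buffer: among left pixels mapping to the same right column,
    # only the nearest (largest disparity) stays visible
    u <- round(src)
    for (r in seq_len(height)) {
      ur <- u[r, ]; dr <- disp[r, ]
      ok <- valid[r, ]
      if (!any(ok)) next
      best <- tapply(dr[ok], ur[ok], max)
      keep <- dr[ok] >= (best[as.character(ur[ok])] - 1e-9)
      ok[ok] <- keep
      valid[r, ] <- ok
    }
    stereo_sample(left, right, disp, valid)
  })
}

#' Generate an elongated tool-like binary mask
#'
#' The union of `n_tools` randomly posed capsules (a rectangle capped by
#' semicircles) entering from an image border, emulating the elongated,
#' border-entering silhouettes of laparoscopic instruments.  Generator
#' proportions are fixed so that two tools cover on average about 15% of the
#' frame, the class-balance statistic of typical instrument datasets.
#'
#' @param height,width mask size
#' @param n_tools number of capsules (0 gives an empty mask)
#' @param seed integer seed
#' @return H x W logical matrix
#' @export
generate_instrument_mask <- function(height, width, n_tools, seed) {
  if (n_tools < 0) stop("n_tools must be non-negative")
  mask <- matrix(FALSE, height, width)
  if (n_tools == 0) return(mask)
  with_local_seed(seed, {
    xg <- matrix(rep(seq_len(width), each = height), height, width)
    yg <- matrix(rep(seq_len(height), times = width), height, width)
    m <- min(height, width)
    for (t in seq_len(n_tools)) {
      side <- sample(4L, 1L)             # 1 left, 2 right, 3 top, 4 bottom
      if (side == 1L) { p0 <- c(1, stats::runif(1, 1, height)); inward <- 0 }
      else if (side == 2L) { p0 <- c(width, stats::runif(1, 1, height)); inward <- pi }
      else if (side == 3L) { p0 <- c(stats::runif(1, 1, width), 1); inward <- pi / 2 }
      else { p0 <- c(stats::runif(1, 1, width), height); inward <- -pi / 2 }
      ang <- inward + stats::runif(1, -pi / 4, pi / 4)
      len <- stats::runif(1, 0.6, 1.1) * m
      r <- stats::runif(1, 0.04, 0.07) * m
      p1 <- p0 + len * c(cos(ang), sin(ang))
      # distance from each pixel to the segment p0-p1
      vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
      tt <- ((xg - p0[1]) * vx + (yg - p0[2]) * vy) / (vx^2 + vy^2)
      tt <- pmin(pmax(tt, 0), 1)
      dist2 <- (xg - (p0[1] + tt * vx))^2 + (yg - (p0[2] + tt * vy))^2
      mask <- mask | (dist2 <= r^2)
    }
    mask
  })
}
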