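# Elementwise and structural primitives for the autodiff engine.
# Every op accepts nodes or plain arrays and returns a node only while a tape
# is recording and a parent requires gradients.

ag_add <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_op(va + vb, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_op(va - vb, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_op(va * vb, list(a, b), function(g) list(g * vb, g * va))
}

ag_div <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_op(va / vb, list(a, b), function(g) list(g / vb, -g * va / (vb * vb)))
}

# scale/shift by plain constants
ag_scale <- function(a, k) {
  va <- ag_value(a)
  ag_op(va * k, list(a), function(g) list(g * k))
}

ag_addc <- function(a, c) {
  va <- ag_value(a)
  ag_op(va + c, list(a), function(g) list(g))
}

ag_square <- function(a) {
  va <- ag_value(a)
  ag_op(va * va, list(a), function(g) list(2 * g * va))
}

ag_exp <- function(a) {
  v <- exp(ag_value(a))
  ag_op(v, list(a), function(g) list(g * v))
}

ag_log <- function(a) {
  va <- ag_value(a)
  ag_op(log(va), list(a), function(g) list(g / va))
}

ag_abs <- function(a) {
  va <- ag_value(a)
  ag_op(abs(va), list(a), function(g) list(g * sign(va)))
}

ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ag_value(a)))
  ag_op(v, list(a), function(g) list(g * v * (1 - v)))
}

ag_leaky_relu <- function(a, slope = 0.1) {
  va <- ag_value(a)
  pos <- (va > 0) * 1
  scale <- slope + (1 - slope) * pos
  v <- va * scale
  ag_op(v, list(a), function(g) list(g * scale))
}

ag_relu <- function(a) ag_leaky_relu(a, slope = 0)

# clamp with zero gradient outside [lo, hi]
ag_clip <- function(a, lo, hi) {
  va <- ag_value(a)
  inside <- va >= lo & va <= hi
  v <- pmin(pmax(va, lo), hi)
  dim(v) <- dim(va)
  ag_op(v, list(a), function(g) {
    dg <- g * inside; dim(dg) <- dim(va); list(dg)
  })
}

#' Huber-style smooth L1 transform
#'
#' `0.5 w^2` where `|w| < 1`, `|w| - 0.5` elsewhere; the two branches agree at
#' `|w| = 1`, so the function is C1-continuous.
#' @param w numeric array (or autodiff node)
#' @return array (or node) of the same shape
#' @export
smooth_l1 <- function(w) {
  vw <- ag_value(w)
  aw <- abs(vw)
  small <- (aw < 1) * 1
  v <- small * (0.5 * vw * vw) + (1 - small) * (aw - 0.5)
  ag_op(v, list(w), function(g) list(g * (small * vw + (1 - small) * sign(vw))))
}

ag_mean <- function(a) {
  va <- ag_value(a)
  n <- length(va)
  ag_op(mean(va), list(a), function(g) {
    dg <- array(g / n, dim = if (is.null(dim(va))) length(va) else dim(va)); list(dg)
  })
}

ag_sum <- function(a) {
  va <- ag_value(a)
  ag_op(sum(va), list(a), function(g) {
    dg <- array(g, dim = if (is.null(dim(va))) length(va) else dim(va)); list(dg)
  })
}

# masked mean: mean of a over TRUE entries of plain logical mask
ag_masked_mean <- function(a, mask) {
  va <- ag_value(a)
  n <- sum(mask)
  if (n == 0) stop("masked mean over an empty mask")
  ag_op(sum(va[mask]) / n, list(a), function(g) {
    dg <- array(0, dim(va)); dg[mask] <- g / n; list(dg)
  })
}

# concatenate along the channel (3rd) dimension
ag_concat_c <- function(xs) {
  vs <- lapply(xs, ag_value)
  dims <- vapply(vs, function(v) dim(v)[3], numeric(1))
  H <- dim(vs[[1]])[1]; W <- dim(vs[[1]])[2]
  out <- array(0, c(H, W, sum(dims)))
  at <- 0L
  for (v in vs) { out[, , at + seq_len(dim(v)[3])] <- v; at <- at + dim(v)[3] }
  ag_op(out, xs, function(g) {
    at <- 0L
    lapply(seq_along(vs), function(i) {
      k <- dims[i]
      gi <- g[, , at + seq_len(k), drop = FALSE]
      at <<- at + k
      gi
    })
  })
}

# zero padding on the spatial dims of an H x W x C array
ag_pad_hw <- function(a, pt, pb, pl, pr) {
  va <- ag_value(a)
  d <- dim(va)
  out <- array(0, c(d[1] + pt + pb, d[2] + pl + pr, d[3]))
  out[pt + seq_len(d[1]), pl + seq_len(d[2]), ] <- va
  ag_op(out, list(a), function(g) {
    list(g[pt + seq_len(d[1]), pl + seq_len(d[2]), , drop = FALSE])
  })
}

# insert (stride-1) zeros between rows/cols: H -> (H-1)*s + 1
ag_zero_stuff <- function(a, s) {
  va <- ag_value(a)
  d <- dim(va)
  if (s == 1L) return(a)
  out <- array(0, c((d[1] - 1L) * s + 1L, (d[2] - 1L) * s + 1L, d[3]))
  ri <- seq(1L, by = s, length.out = d[1]); ci <- seq(1L, by = s, length.out = d[2])
  out[ri, ci, ] <- va
  ag_op(out, list(a), function(g) list(g[ri, ci, , drop = FALSE]))
}

# forward difference along columns (x): out has W-1 columns
ag_fdx <- function(a) {
  va <- ag_value(a)
  d <- dim(va); if (is.null(d)) d <- c(length(va), 1L)
  W <- d[2]
  v <- va[, -1L, drop = FALSE] - va[, -W, drop = FALSE]
  ag_op(v, list(a), function(g) {
    dg <- array(0, d)
    dg[, -1L] <- dg[, -1L, drop = FALSE] + g
    dg[, -W] <- dg[, -W, drop = FALSE] - g
    list(dg)
  })
}

# forward difference along rows (y): out has H-1 rows
ag_fdy <- function(a) {
  va <- ag_value(a)
  d <- dim(va); if (is.null(d)) d <- c(length(va), 1L)
  H <- d[1]
  v <- va[-1L, , drop = FALSE] - va[-H, , drop = FALSE]
  ag_op(v, list(a), function(g) {
    dg <- array(0, d)
    dg[-1L, ] <- dg[-1L, , drop = FALSE] + g
    dg[-H, ] <- dg[-H, , drop = FALSE] - g
    list(dg)
  })
}
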