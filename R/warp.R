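# Differentiable horizontal warping and shallow cost volumes — the two
# operators at the heart of cascade stereo matching.

#' Warp a right-view array into the left view using a disparity map
#'
#' For a rectified pair, the scene point seen at left pixel `(x, y)` appears
#' at right pixel `(x - d(x, y), y)`.  The output is the bilinear sample of
#' `source` at that location: `out(x, y, c) = source(x - d, y, c)`, with
#' samples falling outside the image reading as zero.  The operation is
#' differentiable with respect to both the source and the disparity, which is
#' what lets photometric losses train a disparity network.
#'
#' @param source H x W x C array (or H x W matrix) — typically right-view
#'   intensities or features
#' @param disparity H x W non-negative disparity map in pixels at this
#'   resolution
#' @return array of the same shape as `source`
#' @export
warp_right_to_left <- function(source, disparity) {
  vs <- ag_value(source); vd <- ag_value(disparity)
  d <- dim(vs)
  two_d <- length(d) == 2L
  H <- d[1]; W <- d[2]; C <- if (two_d) 1L else d[3]
  dd <- dim(vd)
  if (is.null(dd)) dd <- c(length(vd), 1L)
  if (dd[1] != H || dd[2] != W)
    stop(sprintf("disparity is %dx%d but source is %dx%d", dd[1], dd[2], H, W))
  if (any(!is.finite(vd))) stop("disparity contains non-finite values")

  xs <- matrix(rep(seq_len(W), each = H), H, W) - vd   # source column, real
  x0 <- floor(xs)
  w1 <- xs - x0                                        # weight of column x0+1
  m0 <- x0 >= 1 & x0 <= W
  m1 <- (x0 + 1) >= 1 & (x0 + 1) <= W
  i0 <- pmin(pmax(x0, 1), W)
  i1 <- pmin(pmax(x0 + 1, 1), W)
  rows <- matrix(rep(seq_len(H), times = W), H, W)
  idx0 <- as.vector(rows + (i0 - 1) * H)               # flat index per pixel
  idx1 <- as.vector(rows + (i1 - 1) * H)

  sm <- matrix(vs, H * W, C)
  v0 <- sm[idx0, , drop = FALSE] * as.vector(m0)
  v1 <- sm[idx1, , drop = FALSE] * as.vector(m1)
  om <- v0 * as.vector(1 - w1) + v1 * as.vector(w1)
  out <- if (two_d) array(om, c(H, W)) else array(om, c(H, W, C))

  ag_op(out, list(source, disparity), function(g) {
    gm <- matrix(g, H * W, C)
    dsrc <- NULL
    if (ag_requires_grad(source)) {
      c0 <- gm * as.vector((1 - w1) * m0)
      c1 <- gm * as.vector(w1 * m1)
      acc <- rowsum(rbind(c0, c1), group = c(idx0, idx1))
      ds <- matrix(0, H * W, C)
      ds[as.integer(rownames(acc)), ] <- acc
      dsrc <- if (two_d) array(ds, c(H, W)) else array(ds, c(H, W, C))
    }
    ddisp <- NULL
    if (ag_requires_grad(disparity)) {
      # d out / d xs = v1 - v0 (within the bilinear cell); xs = x - d
      ddisp_flat <- -rowSums(gm * (v1 - v0))
      ddisp <- array(ddisp_flat, c(H, W))
    }
    list(dsrc, ddisp)
  })
}

#' Build a shallow matching cost volume from pre-aligned feature maps
#'
#' For each integer offset `o` the candidate right feature is the aligned map
#' shifted by `o` columns (zero-filled outside the image), and the cost is
#' the mean over channels of the element-wise product with the left feature:
#' `cost(x, y, k) = mean_c left(x, y, c) * right(x - o_k, y, c)`.
#' Mean-of-products (rather than a dot product) keeps activations small.
#'
#' @param left_feat H x W x C left feature map
#' @param right_feat_aligned H x W x C right feature map, already pre-aligned
#'   by a coarser disparity estimate (or raw at the coarsest scale)
#' @param offsets sorted integer offsets, e.g. `-2:2` or `0:10`
#' @return object of class `cost_volume`: H x W x D array with attribute
#'   `offsets`
#' @export
build_cost_volume <- function(left_feat, right_feat_aligned, offsets) {
  if (length(offsets) == 0L) stop("offsets must be a non-empty integer vector")
  if (is.unsorted(offsets)) stop("offsets must be sorted ascending")
  vl <- ag_value(left_feat); vr <- ag_value(right_feat_aligned)
  d <- dim(vl)
  if (!identical(dim(vr), d)) stop("left and right feature shapes differ")
  H <- d[1]; W <- d[2]; C <- d[3]
  D <- length(offsets)
  offsets <- as.integer(offsets)

  shift_cols <- function(a, o) {
    # out(x) = a(x - o), zero outside
    out <- array(0, dim(a))
    if (o >= 0L) {
      if (o < W) out[, (o + 1L):W, ] <- a[, 1L:(W - o), , drop = FALSE]
    } else {
      if (-o < W) out[, 1L:(W + o), ] <- a[, (1L - o):W, , drop = FALSE]
    }
    out
  }

  vol <- array(0, c(H, W, D))
  for (k in seq_len(D)) {
    rs <- shift_cols(vr, offsets[k])
    vol[, , k] <- rowMeans(matrix(vl * rs, H * W, C)) # mean across channels
  }
  out <- ag_op(vol, list(left_feat, right_feat_aligned), function(g) {
    dl <- if (ag_requires_grad(left_feat)) array(0, d) else NULL
    dr <- if (ag_requires_grad(right_feat_aligned)) array(0, d) else NULL
    for (k in seq_len(D)) {
      gk <- array(g[, , k], c(H, W)) / C
      if (!is.null(dl)) {
        rs <- shift_cols(vr, offsets[k])
        dl <- dl + rs * as.vector(gk)
      }
      if (!is.null(dr)) {
        contrib <- vl * as.vector(gk)             # at left positions x
        dr <- dr + shift_cols(contrib, -offsets[k])
      }
    }
    list(dl, dr)
  })
  if (!is_ag(out)) {
    attr(out, "offsets") <- offsets
    class(out) <- c("cost_volume", class(out))
  } else attr(out$value, "offsets") <- offsets
  out
}
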