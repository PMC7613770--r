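# Convolutional primitives built on im2col + BLAS matrix products.
#
# Layout conventions (all our own, used consistently everywhere):
#   activations: H x W x C arrays, column-major;
#   conv weights: (k*k*Cin) x Cout matrices whose rows enumerate the patch in
#     (dh fastest, then dw, then input channel) order;
#   output positions are enumerated column-major (h fastest) so a matrix of
#     shape (Ho*Wo) x Cout reshapes straight into an Ho x Wo x Cout array.

.ag_cache <- new.env(parent = emptyenv())

# Gather-index matrix mapping each output position to the flat indices of its
# receptive field inside the padded input.  Cached per configuration.
im2col_index <- function(Hp, Wp, Cin, k, stride) {
  key <- paste(Hp, Wp, Cin, k, stride, sep = "_")
  hit <- .ag_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  # top-left corner (1-based) of each patch, h fastest
  h0 <- rep(seq(1L, by = stride, length.out = Ho), times = Wo)
  w0 <- rep(seq(1L, by = stride, length.out = Wo), each = Ho)
  corner <- h0 + (w0 - 1L) * Hp                       # length Ho*Wo
  dh <- rep(seq_len(k) - 1L, times = k)
  dw <- rep(seq_len(k) - 1L, each = k)
  patch <- dh + dw * Hp                                # length k*k
  plane <- (seq_len(Cin) - 1L) * (Hp * Wp)             # channel offsets
  off <- as.vector(outer(patch, plane, `+`))           # k*k*Cin
  idx <- outer(corner, off, `+`)                       # (Ho*Wo) x (k*k*Cin)
  # store dimensionless so x[idx] always means flat indexing
  out <- list(idx = as.vector(idx), nr = nrow(idx), nc = ncol(idx), Ho = Ho, Wo = Wo)
  .ag_cache[[key]] <- out
  out
}

#' 2-D convolution (cross-correlation) with zero padding
#' @param x H x W x Cin array or node
#' @param W weight node/matrix of shape (k*k*Cin) x Cout
#' @param b optional bias node/vector of length Cout (NULL for none)
#' @param k kernel size, stride stride, pad symmetric zero padding
#' @return Ho x Wo x Cout array or node
#' @keywords internal
ag_conv2d <- function(x, W, b = NULL, k = 3L, stride = 1L, pad = 1L) {
  vx <- ag_value(x); vW <- ag_value(W)
  d <- dim(vx)
  Cin <- d[3]
  if (nrow(vW) != k * k * Cin)
    stop(sprintf("conv weight rows %d do not match k*k*Cin = %d", nrow(vW), k * k * Cin))
  if (pad > 0L) {
    xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, Cin))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- vx
  } else xp <- vx
  Hp <- dim(xp)[1]; Wp <- dim(xp)[2]
  ii <- im2col_index(Hp, Wp, Cin, k, stride)
  col <- xp[ii$idx]
  dim(col) <- c(ii$nr, ii$nc)
  y <- col %*% vW
  if (!is.null(b)) y <- sweep(y, 2L, ag_value(b), `+`)
  out <- y
  dim(out) <- c(ii$Ho, ii$Wo, ncol(vW))
  parents <- list(x, W, b)
  Cout <- ncol(vW)
  ag_op(out, parents, function(g) {
    gm <- g
    dim(gm) <- c(ii$Ho * ii$Wo, Cout)
    dW <- crossprod(col, gm)
    db <- if (is.null(b)) NULL else colSums(gm)
    dx <- NULL
    if (ag_requires_grad(x)) {
      # dL/dx_padded = full correlation of the (zero-stuffed) output gradient
      # with the 180-degree-rotated kernel, channels swapped — all BLAS.
      garr <- array(g, c(ii$Ho, ii$Wo, Cout))
      if (stride > 1L) {
        gs <- array(0, c((ii$Ho - 1L) * stride + 1L, (ii$Wo - 1L) * stride + 1L, Cout))
        gs[seq(1L, by = stride, length.out = ii$Ho),
           seq(1L, by = stride, length.out = ii$Wo), ] <- garr
        garr <- gs
      }
      eh <- Hp - (dim(garr)[1] + k - 1L)   # stride remainder zeros
      ew <- Wp - (dim(garr)[2] + k - 1L)
      gp <- array(0, c(dim(garr)[1] + 2L * (k - 1L) + eh,
                       dim(garr)[2] + 2L * (k - 1L) + ew, Cout))
      gp[(k - 1L) + seq_len(dim(garr)[1]), (k - 1L) + seq_len(dim(garr)[2]), ] <- garr
      Wrot <- rotate_weight(vW, k, Cin, Cout)
      jj <- im2col_index(dim(gp)[1], dim(gp)[2], Cout, k, 1L)
      gcol <- gp[jj$idx]
      dim(gcol) <- c(jj$nr, jj$nc)
      dxp <- gcol %*% Wrot
      dim(dxp) <- c(Hp, Wp, Cin)
      dx <- if (pad > 0L) dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE] else dxp
    }
    list(dx, dW, db)
  })
}

# Reindex a (k*k*Cin) x Cout weight matrix into the (k*k*Cout) x Cin matrix
# of the 180-degree-rotated, channel-swapped kernel used by the conv input
# gradient.  Cached per configuration.
rotate_weight <- function(vW, k, Cin, Cout) {
  key <- paste("rot", k, Cin, Cout, sep = "_")
  perm <- .ag_cache[[key]]
  if (is.null(perm)) {
    # target row order: dh' fastest, then dw', then cout; column: cin
    dhp <- rep(seq_len(k) - 1L, times = k)
    dwp <- rep(seq_len(k) - 1L, each = k)
    src_patch <- (k - 1L - dhp) + (k - 1L - dwp) * k          # rotated taps
    perm <- list(patch = src_patch)
    .ag_cache[[key]] <- perm
  }
  out <- matrix(0, k * k * Cout, Cin)
  for (co in seq_len(Cout)) {
    wc <- matrix(vW[, co], k * k, Cin)                         # taps x cin
    out[(co - 1L) * k * k + seq_len(k * k), ] <- wc[perm$patch + 1L, , drop = FALSE]
  }
  out
}

#' Transposed 2-D convolution (kernel 4, stride 2, padding 1 by default)
#'
#' Implemented as zero-stuffing + padding + an ordinary convolution over the
#' layer's own weight tensor, so gradients come from the underlying ops.
#' Doubles the spatial dimensions with the default geometry.
#' @keywords internal
ag_conv_transpose2d <- function(x, W, b = NULL, k = 4L, stride = 2L, pad = 1L) {
  stuffed <- ag_zero_stuff(x, stride)
  extra <- k - 1L - pad
  d <- dim(ag_value(x))
  # output size (H-1)*stride - 2*pad + k; right/bottom may need one extra zero
  target_h <- (d[1] - 1L) * stride - 2L * pad + k
  sh <- (d[1] - 1L) * stride + 1L
  pb <- target_h - sh - extra + (k - 1L)  # bottom pad so conv output hits target
  target_w <- (d[2] - 1L) * stride - 2L * pad + k
  sw <- (d[2] - 1L) * stride + 1L
  pr <- target_w - sw - extra + (k - 1L)
  padded <- ag_pad_hw(stuffed, extra, pb, extra, pr)
  ag_conv2d(padded, W, b, k = k, stride = 1L, pad = 0L)
}

#' Max pooling (kernel 3, stride 2, padding 1 — the ResNet stem configuration)
#' @keywords internal
ag_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  vx <- ag_value(x)
  d <- dim(vx)
  Hp <- d[1] + 2L * pad; Wp <- d[2] + 2L * pad
  xp <- array(-Inf, c(Hp, Wp, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- vx
  ii <- im2col_index(Hp, Wp, 1L, k, stride)
  Ho <- ii$Ho; Wo <- ii$Wo
  out <- array(0, c(Ho, Wo, d[3]))
  argmax <- matrix(0L, Ho * Wo, d[3])
  for (c in seq_len(d[3])) {
    plane <- xp[, , c]
    col <- matrix(plane[ii$idx], ii$nr, ii$nc)
    which_max <- max.col(col, ties.method = "first")
    argmax[, c] <- ii$idx[(which_max - 1L) * ii$nr + seq_len(ii$nr)]
    out[, , c] <- array(col[cbind(seq_len(nrow(col)), which_max)], c(Ho, Wo))
  }
  ag_op(out, list(x), function(g) {
    dxp <- array(0, c(Hp, Wp, d[3]))
    for (c in seq_len(d[3])) {
      gm <- as.vector(g[, , c])
      acc <- rowsum(gm, group = argmax[, c])
      plane <- numeric(Hp * Wp)
      plane[as.integer(rownames(acc))] <- acc
      dxp[, , c] <- dxp[, , c] + array(plane, c(Hp, Wp))
    }
    list(dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE])
  })
}

#' Batch normalization over the spatial dimensions of one sample
#'
#' Normalizes every forward pass with the current sample's per-channel
#' statistics (biased variance) — with single-sample forwards this makes
#' training and inference behave identically while keeping inference a
#' deterministic function of the input.  Training mode additionally updates
#' the layer's running averages, which are stored in checkpoints.
#' @param state environment holding `running_mean`, `running_var`
#' @keywords internal
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         eps = 1e-5, momentum = 0.1) {
  vx <- ag_value(x); vg <- ag_value(gamma); vb <- ag_value(beta)
  d <- dim(vx)
  m <- d[1] * d[2]
  xm <- matrix(vx, m, d[3])
  # normalization always uses the current sample's statistics (the engine
  # forwards one sample at a time, so train and inference behavior match
  # exactly and inference stays a deterministic function of the input);
  # training mode additionally maintains running averages for checkpoints
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu, `-`)
  var <- colMeans(xc * xc)
  if (training) {
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * var
  }
  inv <- 1 / sqrt(var + eps)
  xhat <- sweep(xc, 2L, inv, `*`)
  y <- sweep(sweep(xhat, 2L, vg, `*`), 2L, vb, `+`)
  out <- array(y, d)
  ag_op(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, m, d[3])
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    gh <- sweep(gm, 2L, vg, `*`)   # dL/dxhat
    t1 <- colMeans(gh)
    t2 <- colMeans(gh * xhat)
    dx <- sweep(sweep(gh, 2L, t1, `-`) - sweep(xhat, 2L, t2, `*`), 2L, inv, `*`)
    list(array(dx, d), dgamma, dbeta)
  })
}

# Sparse bilinear x2 upsampling operator (half-pixel-centre convention),
# cached per input size.  Works on H x W matrices and H x W x C arrays.
bilinear_x2_matrix <- function(H, W) {
  key <- paste("up2", H, W, sep = "_")
  hit <- .ag_cache[[key]]
  if (!is.null(hit)) return(hit)
  P <- interp_matrix(2L * H, 2L * W, H, W)
  .ag_cache[[key]] <- P
  P
}

# General sparse bilinear interpolation matrix resampling an Hs x Ws grid to
# Ht x Wt with the half-pixel-centre (align_corners = FALSE) convention.
interp_matrix <- function(Ht, Wt, Hs, Ws) {
  sy <- Hs / Ht; sx <- Ws / Wt
  ty <- (seq_len(Ht) - 0.5) * sy - 0.5 + 1  # source row coord, 1-based
  tx <- (seq_len(Wt) - 0.5) * sx - 0.5 + 1
  y0 <- pmin(pmax(floor(ty), 1), Hs); y1 <- pmin(y0 + 1, Hs)
  x0 <- pmin(pmax(floor(tx), 1), Ws); x1 <- pmin(x0 + 1, Ws)
  wy <- pmin(pmax(ty - y0, 0), 1); wx <- pmin(pmax(tx - x0, 0), 1)
  tgt <- seq_len(Ht * Wt)  # target pixels, h fastest
  Y0 <- rep(y0, times = Wt); Y1 <- rep(y1, times = Wt)
  WY <- rep(wy, times = Wt)
  X0 <- rep(x0, each = Ht); X1 <- rep(x1, each = Ht)
  WX <- rep(wx, each = Ht)
  i <- rep(tgt, 4L)
  j <- c(Y0 + (X0 - 1) * Hs, Y1 + (X0 - 1) * Hs, Y0 + (X1 - 1) * Hs, Y1 + (X1 - 1) * Hs)
  v <- c((1 - WY) * (1 - WX), WY * (1 - WX), (1 - WY) * WX, WY * WX)
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(Ht * Wt, Hs * Ws))
}

#' Bilinear x2 upsampling of an H x W (or H x W x C) array, differentiable
#' @keywords internal
ag_upsample_x2 <- function(x) {
  vx <- ag_value(x)
  d <- dim(vx)
  two_d <- is.na(d[3]) || length(d) == 2L
  H <- d[1]; W <- d[2]; C <- if (two_d) 1L else d[3]
  P <- bilinear_x2_matrix(H, W)
  xm <- matrix(vx, H * W, C)
  ym <- as.matrix(P %*% xm)
  out <- if (two_d) array(ym, c(2L * H, 2L * W)) else array(ym, c(2L * H, 2L * W, C))
  ag_op(out, list(x), function(g) {
    gm <- matrix(g, 4L * H * W, C)
    dx <- as.matrix(Matrix::crossprod(P, gm))
    list(if (two_d) array(dx, c(H, W)) else array(dx, c(H, W, C)))
  })
}

#' Differentiable bilinear resize to an arbitrary target size
#' @keywords internal
ag_resize_bilinear <- function(x, Ht, Wt) {
  vx <- ag_value(x)
  d <- dim(vx)
  two_d <- length(d) == 2L
  C <- if (two_d) 1L else d[3]
  key <- paste("rs", d[1], d[2], Ht, Wt, sep = "_")
  P <- .ag_cache[[key]]
  if (is.null(P)) {
    P <- interp_matrix(Ht, Wt, d[1], d[2])
    .ag_cache[[key]] <- P
  }
  ym <- as.matrix(P %*% matrix(vx, d[1] * d[2], C))
  out <- if (two_d) array(ym, c(Ht, Wt)) else array(ym, c(Ht, Wt, C))
  ag_op(out, list(x), function(g) {
    gm <- matrix(g, Ht * Wt, C)
    dx <- as.matrix(Matrix::crossprod(P, gm))
    list(if (two_d) array(dx, c(d[1], d[2])) else array(dx, c(d[1], d[2], C)))
  })
}

#' Uniform k x k local mean ("valid" region), per channel, via integral images
#' @keywords internal
ag_boxmean <- function(x, k = 11L) {
  vx <- ag_value(x)
  d <- dim(vx)
  if (d[1] < k || d[2] < k) stop("box window larger than image")
  C <- if (length(d) == 3L) d[3] else 1L
  Ho <- d[1] - k + 1L; Wo <- d[2] - k + 1L
  # valid-mode k x k box sum via an integral image; divides by k^2 at the end
  box_valid <- function(plane) {
    H <- nrow(plane); W <- ncol(plane)
    S <- matrix(0, H + 1L, W + 1L)
    S[-1L, -1L] <- t(apply(apply(plane, 2L, cumsum), 1L, cumsum))
    (S[(k + 1):(H + 1), (k + 1):(W + 1), drop = FALSE] -
       S[1:(H - k + 1), (k + 1):(W + 1), drop = FALSE] -
       S[(k + 1):(H + 1), 1:(W - k + 1), drop = FALSE] +
       S[1:(H - k + 1), 1:(W - k + 1), drop = FALSE]) / (k * k)
  }
  out <- array(0, c(Ho, Wo, C))
  for (c in seq_len(C)) out[, , c] <- box_valid(if (length(d) == 3L) vx[, , c] else vx)
  if (length(d) == 2L) out <- array(out, c(Ho, Wo))
  ag_op(out, list(x), function(g) {
    gg <- if (length(d) == 2L) array(g, c(Ho, Wo, 1L)) else g
    dx <- array(0, c(d[1], d[2], C))
    for (c in seq_len(C)) {
      # adjoint of the valid box mean: each input pixel averages the gradient
      # of every window containing it = valid box sum of the zero-padded grad
      padded <- matrix(0, Ho + 2L * (k - 1L), Wo + 2L * (k - 1L))
      padded[k:(k + Ho - 1L), k:(k + Wo - 1L)] <- gg[, , c]
      dx[, , c] <- box_valid(padded)
    }
    list(if (length(d) == 2L) array(dx, c(d[1], d[2])) else dx)
  })
}
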