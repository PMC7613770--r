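# Ground-truth geometry: disparity synthesis from 3-D point maps via dual
# projection, plus the deterministic image-conditioning steps (de-interlacing
# and black-border crop/resize).

#' Construct a rectified stereo rig from two 3x4 projection matrices
#'
#' Rectification demands that both projections assign every 3-D point the
#' same image row; this is asserted at construction on a cloud of random
#' points (row difference < 1e-9).
#' @param P_left,P_right 3 x 4 projection matrices (pixels)
#' @param image_size `c(height, width)` of the rectified views
#' @return a `rectified_rig`
#' @export
rectified_rig <- function(P_left, P_right, image_size) {
  stopifnot(all(dim(P_left) == c(3, 4)), all(dim(P_right) == c(3, 4)),
            length(image_size) == 2)
  pts <- rbind(matrix(stats::rnorm(300, sd = 50), 3, 100) + c(0, 0, 200), 1)
  pl <- P_left %*% pts; pr <- P_right %*% pts
  rows_l <- pl[2, ] / pl[3, ]; rows_r <- pr[2, ] / pr[3, ]
  if (max(abs(rows_l - rows_r)) >= 1e-9)
    stop("projections do not share image rows: the pair is not rectified")
  structure(list(P_left = P_left, P_right = P_right,
                 image_size = as.integer(image_size)),
            class = "rectified_rig")
}

#' Build a rectified rig from pinhole parameters
#' @param focal_px focal length (pixels); cx,cy principal point (pixels)
#' @param baseline_mm baseline (mm), right camera shifted along +x
#' @param image_size `c(height, width)`
#' @return a `rectified_rig`
#' @export
pinhole_rig <- function(focal_px, cx, cy, baseline_mm, image_size) {
  K <- matrix(c(focal_px, 0, 0, 0, focal_px, 0, cx, cy, 1), 3, 3)
  P_left <- cbind(K, c(0, 0, 0))
  P_right <- cbind(K, K %*% c(-baseline_mm, 0, 0))
  rectified_rig(P_left, P_right, image_size)
}

#' Project a 3-D point cloud into a sparse disparity map
#'
#' Every point (millimetres, left camera frame) is projected into both
#' rectified views; the horizontal displacement of the two projections is
#' the disparity, stored at the rounded left-view pixel.  When several
#' points land on one pixel the largest disparity (nearest point) wins.
#' Points behind the camera or projecting outside the image are dropped and
#' counted.
#' @param points N x 3 matrix of 3-D points (mm)
#' @param rig a [rectified_rig()]
#' @return list with `disparity` (H x W, NA where no point), `valid`, and
#'   `n_dropped`
#' @export
points_to_disparity <- function(points, rig) {
  stopifnot(inherits(rig, "rectified_rig"), ncol(points) == 3)
  H <- rig$image_size[1]; W <- rig$image_size[2]
  disparity <- matrix(NA_real_, H, W)
  n <- nrow(points)
  if (n == 0) return(list(disparity = disparity, valid = is.finite(disparity),
                          n_dropped = 0L))
  Ph <- t(cbind(points, 1))
  pl <- rig$P_left %*% Ph
  pr <- rig$P_right %*% Ph
  keep <- is.finite(colSums(Ph)) & pl[3, ] > 0 & pr[3, ] > 0
  xl <- pl[1, ] / pl[3, ]; yl <- pl[2, ] / pl[3, ]
  xr <- pr[1, ] / pr[3, ]
  col <- round(xl) + 1  # projections use 0-based pixel centres
  row <- round(yl) + 1
  keep <- keep & col >= 1 & col <= W & row >= 1 & row <= H
  d <- xl - xr
  n_dropped <- sum(!keep)
  if (any(keep)) {
    ord <- order(d[keep])               # ascending: largest disparity written last
    ri <- row[keep][ord]; ci <- col[keep][ord]; di <- d[keep][ord]
    disparity[cbind(ri, ci)] <- di
  }
  list(disparity = disparity, valid = is.finite(disparity), n_dropped = n_dropped)
}

#' Back-project a disparity map to a 3-D point cloud (testing oracle)
#' @param disparity H x W map; rig a `rectified_rig` built by [pinhole_rig()]
#' @param focal_px,cx,cy,baseline_mm the pinhole parameters used for the rig
#' @return N x 3 matrix of points at valid pixels
#' @export
disparity_to_points <- function(disparity, focal_px, cx, cy, baseline_mm) {
  H <- nrow(disparity); W <- ncol(disparity)
  idx <- which(is.finite(disparity) & disparity > 0, arr.ind = TRUE)
  d <- disparity[idx]
  Z <- focal_px * baseline_mm / d
  X <- ((idx[, 2] - 1) - cx) * Z / focal_px
  Y <- ((idx[, 1] - 1) - cy) * Z / focal_px
  cbind(X, Y, Z)
}

#' Replace interlacing artifacts by interpolating odd rows
#'
#' Rows 2, 4, ... (the second field) are replaced by the bilinear average of
#' their even-row neighbours; even rows are untouched, and the output size
#' is unchanged.  The operation is idempotent.
#' @param image H x W x 3 array (H even)
#' @return array of the same shape
#' @export
deinterlace <- function(image) {
  d <- dim(image)
  H <- d[1]
  if (H %% 2 != 0) stop("deinterlace requires an even number of rows")
  out <- image
  odd <- seq(2L, H, by = 2L)       # rows to rebuild
  above <- odd - 1L
  below <- pmin(odd + 1L, H - 1L)  # last rebuilt row only has the row above
  out[odd, , ] <- (image[above, , , drop = FALSE] + image[below, , , drop = FALSE]) / 2
  out
}

#' Crop black borders and resize to a target resolution
#'
#' Finds the tight bounding box of pixels whose luminance (channel mean)
#' exceeds `border_threshold`, crops to it, and bilinearly resizes to
#' `target` (width, height).
#' @param frame H' x W' x 3 array
#' @param target `c(width, height)` of the output
#' @param border_threshold luminance level below which a pixel counts as
#'   black border (default 8/255; a threshold of 0 on a noisy border crops
#'   nothing, which is why it is configurable)
#' @return target-sized H x W x 3 array
#' @export
crop_and_resize <- function(frame, target = c(1280L, 1024L),
                            border_threshold = 8 / 255) {
  lum <- (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
  content <- lum > border_threshold
  if (!any(content)) stop("frame has no content above the border threshold")
  rows <- range(which(rowSums(content) > 0))
  cols <- range(which(colSums(content) > 0))
  cropped <- frame[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  resize_bilinear(cropped, height = target[2], width = target[1])
}

#' Bilinear resize of an H x W x C array (half-pixel-centre convention)
#' @param image array; height,width target size
#' @return resized array
#' @export
resize_bilinear <- function(image, height, width) {
  d <- dim(image)
  two_d <- length(d) == 2L
  C <- if (two_d) 1L else d[3]
  P <- interp_matrix(height, width, d[1], d[2])
  ym <- as.matrix(P %*% matrix(image, d[1] * d[2], C))
  if (two_d) array(ym, c(height, width)) else array(ym, c(height, width, C))
}
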