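# Evaluation metrics: end-point error, Bad3, depth conversion and depth MAE,
# IoU, and the ground-truth coverage filter.

#' Camera rig parameters for depth conversion
#' @param focal_px focal length in pixels (> 0)
#' @param baseline_mm stereo baseline in millimetres (> 0)
#' @return a `camera_rig` list
#' @export
camera_rig <- function(focal_px, baseline_mm) {
  if (focal_px <= 0 || baseline_mm <= 0)
    stop("focal length and baseline must be strictly positive")
  structure(list(focal_px = focal_px, baseline_mm = baseline_mm),
            class = "camera_rig")
}

check_valid_metric <- function(valid) {
  if (!any(valid)) stop("metric undefined: no valid pixels")
}

#' End-point error (mean absolute disparity error, pixels)
#' @param pred,gt H x W disparity maps
#' @param valid H x W logical mask (NULL means all valid)
#' @return scalar EPE in pixels
#' @export
epe <- function(pred, gt, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(gt), ncol(gt))
  check_valid_metric(valid)
  mean(abs(pred[valid] - gt[valid]))
}

#' Bad3: percentage of pixels whose disparity error exceeds 3 pixels
#'
#' The comparison is strict, so an error of exactly 3 px does not count.
#' @inheritParams epe
#' @return percentage in `[0, 100]`
#' @export
bad3 <- function(pred, gt, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(gt), ncol(gt))
  check_valid_metric(valid)
  100 * mean(abs(pred[valid] - gt[valid]) > 3)
}

#' Convert disparity to depth for a rectified rig
#'
#' `depth = focal_px * baseline_mm / disparity`.  Disparities at or below
#' `d_floor` would blow up to implausible depths and are marked invalid
#' rather than converted.
#' @param disparity H x W map in pixels
#' @param rig a [camera_rig()]
#' @param d_floor minimum disparity considered convertible (pixels)
#' @return list with `depth` (mm; NA where invalid) and `valid`
#' @export
disparity_to_depth <- function(disparity, rig, d_floor = 0.5) {
  stopifnot(inherits(rig, "camera_rig"))
  valid <- is.finite(disparity) & disparity > d_floor
  depth <- matrix(NA_real_, nrow(disparity), ncol(disparity))
  depth[valid] <- rig$focal_px * rig$baseline_mm / disparity[valid]
  list(depth = depth, valid = valid)
}

#' Mean absolute depth error in millimetres
#' @param pred_depth,gt_depth H x W depth maps in mm (NA allowed)
#' @param valid logical mask of jointly valid pixels (NULL: finite entries)
#' @return scalar MAE in mm
#' @export
depth_mae <- function(pred_depth, gt_depth, valid = NULL) {
  joint <- is.finite(pred_depth) & is.finite(gt_depth)
  if (!is.null(valid)) joint <- joint & valid
  check_valid_metric(joint)
  mean(abs(pred_depth[joint] - gt_depth[joint]))
}

#' Intersection-over-union (Jaccard index) of two binary masks
#'
#' Two empty masks agree perfectly on the absence of foreground and score 1.
#' @param pred_mask,gt_mask H x W logical masks of identical shape
#' @return scalar in `[0, 1]`
#' @export
iou <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) stop("mask shapes differ")
  u <- sum(pred_mask | gt_mask)
  if (u == 0) return(1.0)
  sum(pred_mask & gt_mask) / u
}

#' Ground-truth coverage filter
#'
#' A frame enters evaluation only when its valid ground-truth annotation
#' strictly exceeds the threshold fraction of the image (default 10%).
#' @param gt_valid H x W logical ground-truth validity map
#' @param threshold_fraction strict lower bound on coverage
#' @return logical scalar
#' @export
coverage_filter <- function(gt_valid, threshold_fraction = 0.10) {
  mean(gt_valid) > threshold_fraction
}

#' Evaluate a set of predictions against ground truth
#'
#' Applies the coverage filter per frame, then aggregates EPE, Bad3, depth
#' MAE (given a rig) and IoU (given masks) across the retained frames.
#' @param frames list of lists with `pred`, `gt`, `valid`, optionally
#'   `pred_mask`, `gt_mask`
#' @param rig optional [camera_rig()] enabling depth MAE
#' @param coverage_threshold strict coverage fraction for frame admission
#' @return list with per-frame and aggregate metrics
#' @export
evaluate_frames <- function(frames, rig = NULL, coverage_threshold = 0.10) {
  rows <- list()
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    valid <- if (is.null(fr$valid)) matrix(TRUE, nrow(fr$gt), ncol(fr$gt)) else fr$valid
    if (!coverage_filter(valid, coverage_threshold)) next
    row <- list(frame = i, epe = epe(fr$pred, fr$gt, valid),
                bad3 = bad3(fr$pred, fr$gt, valid))
    if (!is.null(rig)) {
      pd <- disparity_to_depth(fr$pred, rig)
      gd <- disparity_to_depth(fr$gt, rig)
      row$depth_mae <- depth_mae(pd$depth, gd$depth, valid & pd$valid & gd$valid)
    }
    if (!is.null(fr$pred_mask) && !is.null(fr$gt_mask))
      row$iou <- iou(fr$pred_mask, fr$gt_mask)
    rows[[length(rows) + 1L]] <- row
  }
  agg <- function(key) {
    v <- unlist(lapply(rows, `[[`, key))
    if (length(v)) mean(v) else NA_real_
  }
  list(per_frame = rows, n_evaluated = length(rows), n_total = length(frames),
       epe = agg("epe"), bad3 = agg("bad3"),
       depth_mae = agg("depth_mae"), iou = agg("iou"))
}
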