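# Frame-level larva tracking: segmentation, tail points, orientation,
# body curvature.
#
# Pixel coordinates are 0-based, x rightward (columns), y downward (rows).
# Frames are plain numeric matrices indexed [row, col]; a multi-well plate
# is tracked one well ROI at a time.

#' Segment a larva in a single frame
#'
#' The frame is background subtracted, Gaussian blurred and thresholded; the
#' centroid is the intensity-weighted center of the largest connected
#' component (ties broken by raster scan order, deterministically). Raising
#' the threshold never grows the mask.
#'
#' @param frame,background Numeric matrices of equal size (grayscale
#'   intensities).
#' @param blur_sigma Gaussian blur standard deviation (px).
#' @param threshold Intensity threshold applied to the blurred difference
#'   image.
#' @return List with `found` (logical), `mask` (logical matrix for the
#'   largest component), `centroid` (`c(x, y)`, 0-based, or `NULL`), and
#'   `intensity` (blurred difference image used for weighting).
#' @export
segment_frame <- function(frame, background, blur_sigma = 1.2, threshold = 20) {
  if (!all(dim(frame) == dim(background))) {
    stop("frame and background must have the same shape")
  }
  diffim <- pmax(frame - background, 0)
  blurred <- if (blur_sigma > 0) EBImage::gblur(diffim, sigma = blur_sigma) else diffim
  bw <- blurred > threshold
  if (!any(bw)) {
    return(list(found = FALSE, mask = bw, centroid = NULL, intensity = blurred))
  }
  labels <- EBImage::bwlabel(bw)
  areas <- tabulate(labels[labels > 0])
  biggest <- which(areas == max(areas))[1] # smallest label id = raster order
  mask <- labels == biggest
  w <- blurred * mask
  tot <- sum(w)
  idx <- which(mask, arr.ind = TRUE)
  wv <- w[mask]
  cy <- sum((idx[, 1] - 1) * wv) / tot
  cx <- sum((idx[, 2] - 1) * wv) / tot
  list(found = TRUE, mask = mask, centroid = c(x = cx, y = cy), intensity = blurred)
}

mask_coords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

#' Fit five tail points along a segmented larva
#'
#' Points step caudally from the centroid along the body at (approximately)
#' equal arc steps, ordered rostral to caudal. The initial direction is
#' toward the mask pixel farthest from the centroid (the tail tip); each
#' subsequent point is the intensity-weighted mean of mask pixels in an
#' annulus ahead of the current point, so the chain follows the bent body.
#'
#' @param mask Logical matrix (single connected component).
#' @param centroid `c(x, y)` from [segment_frame()].
#' @param intensity Optional weighting image (e.g. the blurred difference);
#'   uniform weights if `NULL`.
#' @param step_px Arc step between successive points (px); at 10 px/mm the
#'   default spans a ~3.3 mm tail over five points.
#' @param n_points Number of tail points.
#' @return `n_points` x 2 matrix of (x, y), or `NULL` (degenerate posture)
#'   when the mask cannot hold the chain.
#' @export
fit_tail_points <- function(mask, centroid, intensity = NULL, step_px = 6.5,
                            n_points = 5) {
  pts <- mask_coords(mask)
  if (nrow(pts) < n_points) {
    return(NULL) # degenerate posture: mask too small for the chain
  }
  # squared intensity weights concentrate each step on the backbone ridge
  wts <- if (is.null(intensity)) rep(1, nrow(pts)) else intensity[which(mask)]^2
  d2tip <- (pts[, 1] - centroid[1])^2 + (pts[, 2] - centroid[2])^2
  tip <- pts[which.max(d2tip), ]
  if (sqrt(max(d2tip)) < 0.6 * step_px) {
    return(NULL)
  }
  cur <- c(centroid[1], centroid[2])
  dir <- tip - cur
  dir <- dir / sqrt(sum(dir^2))
  out <- matrix(NA_real_, n_points, 2, dimnames = list(NULL, c("x", "y")))
  max_ang <- cos(100 * pi / 180)
  for (i in seq_len(n_points)) {
    rel_x <- pts[, 1] - cur[1]
    rel_y <- pts[, 2] - cur[2]
    dist <- sqrt(rel_x^2 + rel_y^2)
    along <- (rel_x * dir[1] + rel_y * dir[2]) / pmax(dist, 1e-9)
    sel <- dist >= 0.75 * step_px & dist <= 1.25 * step_px &
      along > (if (i == 1) cos(60 * pi / 180) else max_ang)
    if (!any(sel)) { # widen once near the tail tip
      sel <- dist >= 0.4 * step_px & dist <= 1.8 * step_px & along > max_ang
    }
    if (!any(sel)) {
      return(NULL)
    }
    wsel <- wts[sel]
    nxt <- c(
      sum(pts[sel, 1] * wsel) / sum(wsel),
      sum(pts[sel, 2] * wsel) / sum(wsel)
    )
    step_vec <- nxt - cur
    dir <- step_vec / sqrt(sum(step_vec^2))
    cur <- nxt
    out[i, ] <- nxt
  }
  out
}

#' Heading orientation of a pose
#'
#' The heading is the angle of the vector from the first body point to the
#' centroid (the tail points caudally, so this vector points rostrally), in
#' `(-pi, pi]`.
#'
#' @param centroid `c(x, y)`.
#' @param first_point First (most rostral) tail point, `c(x, y)`.
#' @return Angle in radians, or `NA` if the points coincide.
#' @export
compute_orientation <- function(centroid, first_point) {
  v <- c(centroid[1] - first_point[1], centroid[2] - first_point[2])
  if (all(abs(v) < 1e-12)) {
    return(NA_real_)
  }
  a <- atan2(v[2], v[1])
  if (a == -pi) a <- pi
  a
}

#' Total body curvature of a pose
#'
#' The sum over consecutive point triples (centroid followed by the tail
#' points) of the unsigned angle between successive segment vectors.
#' Invariant under translation and rotation of the pose.
#'
#' @param points Matrix of (x, y) body points ordered rostral to caudal,
#'   typically `rbind(centroid, tail_points)`.
#' @return Total curvature in radians (>= 0), or `NA` when fewer than three
#'   distinct points are available.
#' @export
compute_curvature <- function(points) {
  points <- as.matrix(points)
  keep <- c(TRUE, rowSums(abs(diff(points))) > 1e-12)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 3) {
    return(NA_real_)
  }
  v <- unname(diff(points))
  total <- 0
  for (i in seq_len(nrow(v) - 1)) {
    a <- v[i, ]
    b <- v[i + 1, ]
    total <- total + abs(atan2(a[1] * b[2] - a[2] * b[1], sum(a * b)))
  }
  unname(total)
}

#' Track a stack of frames into a trajectory
#'
#' Runs [segment_frame()], [fit_tail_points()], [compute_orientation()] and
#' [compute_curvature()] on each frame. Frames without a detected object (or
#' with a degenerate posture) yield rows with `NA` pose fields, so gaps
#' propagate rather than abort.
#'
#' @param frames List of numeric matrices.
#' @param background Background matrix (same shape).
#' @param time_ms Frame timestamps (ms), strictly increasing.
#' @param blur_sigma,threshold,step_px See [segment_frame()] and
#'   [fit_tail_points()].
#' @return Data frame with one row per frame: `frame`, `time_ms`, `x`, `y`,
#'   `tail_x1..tail_y5`, `orientation_rad`, `curvature_rad`, `found`.
#' @export
track_frames <- function(frames, background, time_ms = seq_along(frames),
                         blur_sigma = 1.2, threshold = 20, step_px = 6.5) {
  stopifnot(length(time_ms) == length(frames))
  if (is.unsorted(time_ms, strictly = TRUE)) stop("timestamps must be strictly increasing")
  rows <- lapply(seq_along(frames), function(i) {
    seg <- segment_frame(frames[[i]], background, blur_sigma, threshold)
    row <- data.frame(
      frame = i, time_ms = time_ms[i],
      x = NA_real_, y = NA_real_,
      tail_x1 = NA_real_, tail_y1 = NA_real_, tail_x2 = NA_real_,
      tail_y2 = NA_real_, tail_x3 = NA_real_, tail_y3 = NA_real_,
      tail_x4 = NA_real_, tail_y4 = NA_real_, tail_x5 = NA_real_,
      tail_y5 = NA_real_,
      orientation_rad = NA_real_, curvature_rad = NA_real_,
      found = FALSE
    )
    if (!seg$found) {
      return(row)
    }
    row$x <- seg$centroid[1]
    row$y <- seg$centroid[2]
    row$found <- TRUE
    tp <- fit_tail_points(seg$mask, seg$centroid, seg$intensity, step_px)
    if (!is.null(tp)) {
      row[paste0("tail_x", 1:5)] <- tp[, 1]
      row[paste0("tail_y", 1:5)] <- tp[, 2]
      row$orientation_rad <- compute_orientation(seg$centroid, tp[1, ])
      row$curvature_rad <- compute_curvature(rbind(seg$centroid, tp))
    }
    row
  })
  do.call(rbind, rows)
}
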