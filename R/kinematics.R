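# Swim-bout detection and post-stimulus response extraction/classification.

#' Kinematic classification thresholds
#'
#' All thresholds are applied with strict inequality exactly as published:
#' a bout requires per-frame displacement > 0.7 px on at least two
#' consecutive frames; an O-bend requires peak curvature > 1.75 rad; an SLC
#' requires peak curvature > 0.8 rad and latency < 20 ms; a "react"
#' requires peak curvature > 0.5 rad; and a visually evoked movement with
#' latency <= 15 ms is discarded as too early. Equality at a boundary falls
#' to the lower class (an ASR latency of exactly 20 ms is an LLC).
#'
#' @param bout_disp_px Per-frame centroid displacement threshold (px).
#' @param bout_consecutive_frames Frames required above/below threshold to
#'   start/end a bout.
#' @param react_curv_rad Minimum peak curvature for any classified response.
#' @param obend_curv_rad O-bend peak-curvature threshold (dark flash only).
#' @param slc_llc_curv_rad C-start peak-curvature threshold (acoustic).
#' @param slc_latency_ms SLC/LLC latency boundary.
#' @param min_latency_ms "Too early" latency gate for visual stimuli.
#' @param asr_too_early Whether the too-early gate also applies to acoustic
#'   responses (published only for LF/DF; off by default).
#' @param max_missing_fraction Response windows with a larger fraction of
#'   untracked frames are excluded.
#' @return A list of class `kinematic_thresholds`.
#' @export
kinematic_thresholds <- function(bout_disp_px = 0.7,
                                 bout_consecutive_frames = 2,
                                 react_curv_rad = 0.5,
                                 obend_curv_rad = 1.75,
                                 slc_llc_curv_rad = 0.8,
                                 slc_latency_ms = 20,
                                 min_latency_ms = 15,
                                 asr_too_early = FALSE,
                                 max_missing_fraction = 0.2) {
  stopifnot(
    bout_disp_px > 0, bout_consecutive_frames >= 1,
    react_curv_rad > 0,
    react_curv_rad < slc_llc_curv_rad,
    slc_llc_curv_rad < obend_curv_rad,
    slc_latency_ms > 0, min_latency_ms > 0
  )
  structure(
    list(
      bout_disp_px = bout_disp_px,
      bout_consecutive_frames = bout_consecutive_frames,
      react_curv_rad = react_curv_rad,
      obend_curv_rad = obend_curv_rad,
      slc_llc_curv_rad = slc_llc_curv_rad,
      slc_latency_ms = slc_latency_ms,
      min_latency_ms = min_latency_ms,
      asr_too_early = asr_too_early,
      max_missing_fraction = max_missing_fraction
    ),
    class = "kinematic_thresholds"
  )
}

#' Detect swim bouts in a per-frame displacement series
#'
#' A bout starts at the first of at least two consecutive frames whose
#' displacement exceeds the threshold and ends at the frame preceding the
#' first of two consecutive frames at or below it. Single-frame excursions
#' in either direction do not change state. A bout still open at the end of
#' the series is truncated there and flagged.
#'
#' @param displacement Numeric vector of per-frame centroid displacements
#'   (px), uniformly sampled.
#' @param thresholds A [kinematic_thresholds()] object.
#' @return Data frame with one row per bout: `start_frame`, `end_frame`
#'   (1-based indices into `displacement`), `truncated`.
#' @export
#' @examples
#' detect_bouts(c(0, 1, 1, 0.2, 0.1, 0))  # one bout, frames 2-3
detect_bouts <- function(displacement, thresholds = kinematic_thresholds()) {
  if (anyNA(displacement)) stop("displacement series contains NA; split at gaps first")
  k <- thresholds$bout_consecutive_frames
  above <- displacement > thresholds$bout_disp_px
  n <- length(above)
  out_start <- integer(0)
  out_end <- integer(0)
  truncated <- logical(0)
  if (n) {
    r <- rle(above)
    run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    in_bout <- FALSE
    cur_start <- NA_integer_
    for (i in seq_along(r$lengths)) {
      if (!in_bout && r$values[i] && r$lengths[i] >= k) {
        in_bout <- TRUE
        cur_start <- run_start[i]
      } else if (in_bout && !r$values[i] && r$lengths[i] >= k) {
        out_start <- c(out_start, cur_start)
        out_end <- c(out_end, run_start[i] - 1L)
        truncated <- c(truncated, FALSE)
        in_bout <- FALSE
      }
    }
    if (in_bout) {
      out_start <- c(out_start, cur_start)
      out_end <- c(out_end, n)
      truncated <- c(truncated, TRUE)
    }
  }
  data.frame(start_frame = out_start, end_frame = out_end, truncated = truncated)
}

# Per-frame displacement of a centroid track; first frame gets 0.
frame_displacement <- function(x, y) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  c(0, sqrt(diff(x)^2 + diff(y)^2))
}

#' Detect bouts in a trajectory and compute per-bout kinematics
#'
#' Centroid movement is only accumulated within bouts: path distance is the
#' sum of per-frame displacements over the bout, net displacement the chord
#' from the frame before bout start to the bout end.
#'
#' @param traj Data frame with `time_ms`, `x`, `y` for one larva, uniformly
#'   sampled.
#' @param thresholds A [kinematic_thresholds()] object.
#' @return Data frame with one row per bout: frame indices, `start_ms`,
#'   `duration_ms`, `distance_px`, `displacement_px`, `mean_speed_px_ms`,
#'   `truncated`.
#' @export
bouts_from_trajectory <- function(traj, thresholds = kinematic_thresholds()) {
  stopifnot(all(c("time_ms", "x", "y") %in% names(traj)))
  dt <- diff(traj$time_ms)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * max(dt)) {
    stop("trajectory is not uniformly sampled")
  }
  dt <- if (length(dt)) dt[1] else NA_real_
  disp <- frame_displacement(traj$x, traj$y)
  b <- detect_bouts(disp, thresholds)
  if (!nrow(b)) {
    return(cbind(b,
      start_ms = numeric(0), duration_ms = numeric(0),
      distance_px = numeric(0), displacement_px = numeric(0),
      mean_speed_px_ms = numeric(0)
    )[, c(
      "start_frame", "end_frame", "start_ms", "duration_ms",
      "distance_px", "displacement_px", "mean_speed_px_ms", "truncated"
    )])
  }
  dist <- mapply(function(s, e) sum(disp[s:e]), b$start_frame, b$end_frame)
  ref <- pmax(b$start_frame - 1L, 1L)
  net <- sqrt((traj$x[b$end_frame] - traj$x[ref])^2 +
    (traj$y[b$end_frame] - traj$y[ref])^2)
  dur <- (b$end_frame - b$start_frame + 1L) * dt
  data.frame(
    start_frame = b$start_frame,
    end_frame = b$end_frame,
    start_ms = traj$time_ms[b$start_frame],
    duration_ms = dur,
    distance_px = dist,
    displacement_px = pmin(net, dist),
    mean_speed_px_ms = dist / dur,
    truncated = b$truncated
  )
}

wrap_angle <- function(a) {
  # wrap to (-pi, pi]
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

#' Extract post-stimulus response kinematics from a trajectory window
#'
#' Movement onset inside the window is defined by the bout criterion applied
#' at the block frame rate; latency is the time from stimulus onset to the
#' first supra-threshold movement frame. Peak curvature and peak per-frame
#' angular velocity are taken over the whole window; net orientation change
#' is the wrapped magnitude (in `[0, pi]`) between movement onset and end of
#' movement; distance, displacement and duration are measured over the
#' movement, truncated (and flagged) at the window end.
#'
#' @param traj Data frame covering the response window at the block frame
#'   rate, with columns `time_ms`, `x`, `y`, `curvature_rad`,
#'   `orientation_rad`. Untracked frames have `NA` coordinates.
#' @param stimulus One event row (as from [events_of()]); only `onset_ms` is
#'   used.
#' @param record_window_ms Length of the response window (ms).
#' @param thresholds A [kinematic_thresholds()] object.
#' @return One-row data frame of response features (`moved`, `latency_ms`,
#'   `max_curvature_rad`, `max_angular_velocity_rad_per_frame`,
#'   `delta_orientation_rad`, `displacement_px`, `distance_px`,
#'   `duration_ms`, `truncated`, `excluded`).
#' @export
extract_response <- function(traj, stimulus, record_window_ms,
                             thresholds = kinematic_thresholds()) {
  onset <- stimulus$onset_ms[1]
  w <- traj[traj$time_ms >= onset & traj$time_ms <= onset + record_window_ms, , drop = FALSE]
  if (!nrow(w)) stop("trajectory does not cover the response window")
  empty <- data.frame(
    moved = FALSE, latency_ms = NA_real_, max_curvature_rad = NA_real_,
    max_angular_velocity_rad_per_frame = NA_real_,
    delta_orientation_rad = NA_real_, displacement_px = NA_real_,
    distance_px = NA_real_, duration_ms = NA_real_,
    truncated = FALSE, excluded = FALSE
  )
  missing_frac <- mean(is.na(w$x))
  if (missing_frac > thresholds$max_missing_fraction) {
    empty$excluded <- TRUE
    return(empty)
  }
  w <- w[!is.na(w$x), , drop = FALSE]
  empty$max_curvature_rad <- suppressWarnings(max(w$curvature_rad, na.rm = TRUE))
  dori <- abs(wrap_angle(diff(w$orientation_rad)))
  empty$max_angular_velocity_rad_per_frame <-
    if (length(dori)) max(dori, na.rm = TRUE) else NA_real_

  disp <- frame_displacement(w$x, w$y)
  b <- detect_bouts(disp, thresholds)
  if (!nrow(b)) {
    return(empty)
  }
  s <- b$start_frame[1]
  e <- b$end_frame[1]
  dt <- if (nrow(w) > 1) w$time_ms[2] - w$time_ms[1] else NA_real_
  ref <- max(s - 1L, 1L)
  out <- empty
  out$moved <- TRUE
  out$latency_ms <- w$time_ms[s] - onset
  out$delta_orientation_rad <- min(
    abs(wrap_angle(w$orientation_rad[e] - w$orientation_rad[s])), pi
  )
  out$displacement_px <- sqrt((w$x[e] - w$x[ref])^2 + (w$y[e] - w$y[ref])^2)
  out$distance_px <- sum(disp[s:e])
  out$duration_ms <- (e - s + 1L) * dt
  out$truncated <- b$truncated[1]
  out
}

#' Classify a response event
#'
#' Dark/light flash: movements with latency at or below the too-early gate
#' are labeled `too_early`; otherwise a dark-flash response is an `obend`
#' above 1.75 rad peak curvature or a `react` above 0.5 rad, and a
#' light-flash response is a `react` above 0.5 rad. Acoustic: `slc` above
#' 0.8 rad with latency strictly below 20 ms, `llc` above 0.8 rad otherwise,
#' `react` between 0.5 and 0.8 rad. Anything else (including windows with no
#' movement) is `none`. Vectorized; each event receives exactly one label.
#'
#' @param assay Assay label(s): `"LF"`, `"DF"` or `"ASR"`.
#' @param max_curvature_rad Peak curvature per event (rad).
#' @param latency_ms Movement-onset latency per event (`NA` if no movement).
#' @param moved Logical; whether supra-threshold movement occurred.
#' @param thresholds A [kinematic_thresholds()] object.
#' @return Character vector of labels in
#'   `{none, too_early, react, obend, slc, llc}`.
#' @export
classify_response <- function(assay, max_curvature_rad, latency_ms,
                              moved = !is.na(latency_ms),
                              thresholds = kinematic_thresholds()) {
  n <- max(length(assay), length(max_curvature_rad), length(latency_ms), length(moved))
  assay <- rep_len(assay, n)
  mc <- rep_len(max_curvature_rad, n)
  lat <- rep_len(latency_ms, n)
  moved <- rep_len(moved, n)
  if (!all(assay %in% c("LF", "DF", "ASR"))) {
    stop("unknown assay label: ", paste(unique(setdiff(assay, c("LF", "DF", "ASR"))), collapse = ", "))
  }
  th <- thresholds
  label <- rep("none", n)
  visual <- assay %in% c("LF", "DF")
  gate_early <- visual | (assay == "ASR" & th$asr_too_early)
  early <- moved & gate_early & lat <= th$min_latency_ms
  label[early] <- "too_early"
  ok <- moved & !early

  i <- ok & assay == "DF" & mc > th$obend_curv_rad
  label[i] <- "obend"
  i <- ok & assay == "DF" & mc > th$react_curv_rad & mc <= th$obend_curv_rad
  label[i] <- "react"
  i <- ok & assay == "LF" & mc > th$react_curv_rad
  label[i] <- "react"
  i <- ok & assay == "ASR" & mc > th$slc_llc_curv_rad & lat < th$slc_latency_ms
  label[i] <- "slc"
  i <- ok & assay == "ASR" & mc > th$slc_llc_curv_rad & lat >= th$slc_latency_ms
  label[i] <- "llc"
  i <- ok & assay == "ASR" & mc > th$react_curv_rad & mc <= th$slc_llc_curv_rad
  label[i] <- "react"
  label
}

#' Extract and classify all responses of one larva for one assay
#'
#' @param traj Trajectory data frame for one larva with columns `assay`,
#'   `time_ms`, `x`, `y`, `curvature_rad`, `orientation_rad` (times relative
#'   to block start).
#' @param protocol A `protocol`.
#' @param assay `"LF"`, `"DF"` or `"ASR"`.
#' @param thresholds A [kinematic_thresholds()] object.
#' @return Data frame with one row per recorded stimulus: stimulus fields,
#'   response features and `label`.
#' @export
extract_assay_responses <- function(traj, protocol, assay,
                                    thresholds = kinematic_thresholds()) {
  block <- protocol$blocks[[assay]]
  if (is.null(block)) stop("unknown assay label: ", assay)
  ev <- block$events[block$events$recorded & block$events$kind %in%
    c("light_flash", "dark_flash", "acoustic"), , drop = FALSE]
  tr <- traj[traj$assay == assay, , drop = FALSE]
  out <- lapply(seq_len(nrow(ev)), function(i) {
    extract_response(tr, ev[i, ], block$record_window_ms, thresholds)
  })
  out <- do.call(rbind, out)
  out$label <- classify_response(
    assay, out$max_curvature_rad, out$latency_ms, out$moved, thresholds
  )
  cbind(
    ev[, c("block_id", "stimulus_index", "onset_ms", "intensity",
           "prepulse_intensity", "prepulse_lead_ms")],
    out,
    row.names = NULL
  )
}
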