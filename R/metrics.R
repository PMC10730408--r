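# The 94-metric behavioral profile: 60 VMR + 9 LF + 11 DF + 14 ASR.

VMR_BINS <- c(
  "light_on_first_min", "light_on_last_min", "light_on_full",
  "light_off_first_min", "light_off_last_min", "light_off_full"
)
VMR_BASE_METRICS <- c(
  n_bouts = "count", total_distance_px = "px", total_time_moved_ms = "ms",
  avg_speed_px_ms = "px/ms", avg_dist_center_px = "px",
  frac_time_outer_rim = "fraction", avg_bout_distance_px = "px",
  avg_bout_displacement_px = "px", avg_bout_time_ms = "ms",
  avg_bout_speed_px_ms = "px/ms"
)
EVENT_SUMMARY_METRICS <- c(
  freq_react = "fraction", freq_no_movement = "fraction",
  avg_latency_ms = "ms", avg_max_bend_rad = "rad",
  avg_max_angvel_rad_frame = "rad/frame", avg_delta_orientation_rad = "rad",
  avg_displacement_px = "px", avg_distance_px = "px", avg_duration_ms = "ms"
)

#' The behavioral metric registry
#'
#' Ordered descriptors of all 94 metrics: 60 VMR (10 base metrics over six
#' time bins: first minute, last minute and full span of the lights-on and
#' lights-off phases), 9 light-flash, 11 dark-flash (the 9 event summaries
#' plus O-bend frequency and O-bend habituation) and 14 acoustic-startle
#' (the 9 summaries plus SLC frequency, LLC frequency, sensitivity index,
#' prepulse inhibition and habituation).
#'
#' @return Data frame with columns `id`, `assay`, `bin`, `base`, `units`.
#' @export
metric_registry <- function() {
  vmr <- expand.grid(
    base = names(VMR_BASE_METRICS), bin = VMR_BINS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  vmr <- data.frame(
    id = paste("vmr", vmr$bin, vmr$base, sep = "_"),
    assay = "VMR", bin = vmr$bin, base = vmr$base,
    units = unname(VMR_BASE_METRICS[vmr$base]),
    stringsAsFactors = FALSE
  )
  ev <- function(assay, prefix, extra = character(0), extra_units = character(0)) {
    data.frame(
      id = c(paste(prefix, names(EVENT_SUMMARY_METRICS), sep = "_"), extra),
      assay = assay, bin = NA_character_,
      base = c(names(EVENT_SUMMARY_METRICS), sub(paste0(prefix, "_"), "", extra)),
      units = c(unname(EVENT_SUMMARY_METRICS), extra_units),
      stringsAsFactors = FALSE
    )
  }
  reg <- rbind(
    vmr,
    ev("LF", "lf"),
    ev("DF", "df",
      extra = c("df_freq_obend", "df_habituation"),
      extra_units = c("fraction", "fraction")
    ),
    ev("ASR", "asr",
      extra = c(
        "asr_freq_slc", "asr_freq_llc", "asr_sensitivity_index",
        "asr_ppi", "asr_habituation"
      ),
      extra_units = c("fraction", "fraction", "AU", "fraction", "fraction")
    )
  )
  rownames(reg) <- NULL
  stopifnot(nrow(reg) == 94, !anyDuplicated(reg$id))
  reg
}

# Time-weighted position summary over [t0, t1): positions are piecewise
# constant from each sample time to the next.
position_summary <- function(positions, t0, t1, well_radius_px, rim_fraction) {
  t <- positions$time_ms
  seg_start <- pmax(t, t0)
  seg_end <- pmin(c(t[-1], t1), t1)
  w <- pmax(seg_end - seg_start, 0)
  if (sum(w) <= 0) {
    return(c(avg_dist_center_px = NA_real_, frac_time_outer_rim = NA_real_))
  }
  r <- sqrt(positions$x^2 + positions$y^2)
  c(
    avg_dist_center_px = sum(w * r) / sum(w),
    frac_time_outer_rim = sum(w * (r > rim_fraction * well_radius_px)) / sum(w)
  )
}

#' Visual motor response metrics (60)
#'
#' For each of six time bins: bout count, total path distance, total time
#' moved, average speed while moving (total distance over total time
#' moved), time-weighted average distance from the well center, fraction of
#' time spent in the outer rim of the well, and per-bout averages of
#' distance, net displacement, duration and speed. Bouts straddling a bin
#' boundary count toward the bin containing their start. Per-bout averages
#' of an empty bin are missing, and its totals zero.
#'
#' @param bouts Bout table for one larva (columns `start_ms`,
#'   `duration_ms`, `distance_px`, `displacement_px`, `mean_speed_px_ms`),
#'   e.g. from [bouts_from_trajectory()] or a simulated cohort.
#' @param positions Data frame `time_ms`, `x`, `y` of well-centered
#'   positions for the larva (any sampling; treated piecewise constant).
#' @param protocol A `protocol` supplying the lights-on/off phase spans.
#' @param well_radius_px Well radius (the screen's wells are 9 mm across;
#'   45 px at 10 px/mm).
#' @param rim_fraction Radial fraction beyond which a larva counts as in
#'   the outer rim.
#' @return Named numeric vector of the 60 VMR metrics.
#' @export
vmr_metrics <- function(bouts, positions, protocol, well_radius_px = 45,
                        rim_fraction = 2 / 3) {
  phases <- vmr_phases(protocol)
  bins <- list(
    light_on_first_min = c(phases$light$start, phases$light$start + 60000),
    light_on_last_min = c(
      phases$light$start + phases$light$duration - 60000,
      phases$light$start + phases$light$duration
    ),
    light_on_full = c(phases$light$start, phases$light$start + phases$light$duration),
    light_off_first_min = c(phases$dark$start, phases$dark$start + 60000),
    light_off_last_min = c(
      phases$dark$start + phases$dark$duration - 60000,
      phases$dark$start + phases$dark$duration
    ),
    light_off_full = c(phases$dark$start, phases$dark$start + phases$dark$duration)
  )
  out <- numeric(0)
  for (bn in names(bins)) {
    t0 <- bins[[bn]][1]
    t1 <- bins[[bn]][2]
    b <- bouts[!is.null(bouts) & bouts$start_ms >= t0 & bouts$start_ms < t1, , drop = FALSE]
    nb <- nrow(b)
    tot_dist <- sum(b$distance_px)
    tot_time <- sum(b$duration_ms)
    vals <- c(
      n_bouts = nb,
      total_distance_px = tot_dist,
      total_time_moved_ms = tot_time,
      avg_speed_px_ms = if (tot_time > 0) tot_dist / tot_time else NA_real_,
      position_summary(positions, t0, t1, well_radius_px, rim_fraction),
      avg_bout_distance_px = if (nb) mean(b$distance_px) else NA_real_,
      avg_bout_displacement_px = if (nb) mean(b$displacement_px) else NA_real_,
      avg_bout_time_ms = if (nb) mean(b$duration_ms) else NA_real_,
      avg_bout_speed_px_ms = if (nb) mean(b$mean_speed_px_ms) else NA_real_
    )
    names(vals) <- paste("vmr", bn, names(VMR_BASE_METRICS), sep = "_")
    out <- c(out, vals)
  }
  out
}

#' Event summary metrics (9) for one assay
#'
#' Response frequency counts every classified response (`react` and any
#' higher class); no-movement frequency counts windows without
#' supra-threshold movement. Feature averages are taken over events passing
#' the movement and latency gates (moved, not too early); they are missing
#' when no such events exist.
#'
#' @param events Classified response events of one larva for one assay
#'   (rows of [extract_assay_responses()] or a simulated cohort).
#' @param prefix Metric id prefix (`"lf"`, `"df"`, `"asr"`).
#' @return Named numeric vector of 9 metrics.
#' @export
event_summary_metrics <- function(events, prefix) {
  n <- nrow(events)
  if (!n) stop("no stimuli for assay summary")
  responding <- events$label %in% c("react", "obend", "slc", "llc")
  gated <- events$moved & events$label != "too_early"
  g <- events[gated, , drop = FALSE]
  avg <- function(col) if (nrow(g)) mean(g[[col]], na.rm = TRUE) else NA_real_
  vals <- c(
    freq_react = sum(responding) / n,
    freq_no_movement = sum(!events$moved) / n,
    avg_latency_ms = avg("latency_ms"),
    avg_max_bend_rad = avg("max_curvature_rad"),
    avg_max_angvel_rad_frame = avg("max_angular_velocity_rad_per_frame"),
    avg_delta_orientation_rad = avg("delta_orientation_rad"),
    avg_displacement_px = avg("displacement_px"),
    avg_distance_px = avg("distance_px"),
    avg_duration_ms = avg("duration_ms")
  )
  names(vals) <- paste(prefix, names(vals), sep = "_")
  vals
}

# 1 - late/early by default; "literal" reproduces the published text
# (1 - late) / early.
habituation_ratio <- function(late, early, mode = c("conventional", "literal")) {
  mode <- match.arg(mode)
  if (is.na(early) || early == 0) {
    return(NA_real_)
  }
  if (mode == "conventional") 1 - late / early else (1 - late) / early
}

#' Dark-flash metrics (11)
#'
#' The 9 event summaries over all recorded dark flashes, plus O-bend
#' frequency and O-bend habituation (one minus the O-bend frequency over
#' the last recorded 14-flash block divided by that over the first;
#' missing when the first-block frequency is zero).
#'
#' @param events Classified DF response events of one larva (42 recorded
#'   stimuli in the default paradigm).
#' @param habituation_mode `"conventional"` for `1 - late/early`,
#'   `"literal"` for `(1 - late)/early`.
#' @return Named numeric vector of 11 metrics.
#' @export
df_metrics <- function(events, habituation_mode = "conventional") {
  out <- event_summary_metrics(events, "df")
  obend <- events$label == "obend"
  blocks <- sort(unique(events$block_id))
  first_b <- events$block_id == blocks[1]
  last_b <- events$block_id == blocks[length(blocks)]
  c(
    out,
    df_freq_obend = mean(obend),
    df_habituation = habituation_ratio(
      mean(obend[last_b]), mean(obend[first_b]), habituation_mode
    )
  )
}

#' Acoustic startle metrics (14)
#'
#' The 9 event summaries over the ten high-intensity 20 s-ISI stimuli (the
#' no-prepulse pulses of the PPI pattern), plus: SLC and LLC frequency over
#' those stimuli; startle habituation (one minus the SLC frequency over the
#' last 10 stimuli of the 30-stimulus 1 s-ISI train divided by the baseline
#' SLC frequency); prepulse inhibition (one minus the SLC frequency over
#' the ten PPI4 stimuli divided by baseline); and the sensitivity index,
#' the trapezoidal area under SLC frequency versus stimulus intensity at
#' ordinal abscissae 1, 2, 3 (low, medium, high; arbitrary units).
#' Habituation and PPI are missing when the baseline SLC frequency is zero.
#'
#' @param events Classified ASR response events of one larva (100 recorded
#'   stimuli in the default paradigm).
#' @param habituation_mode As in [df_metrics()].
#' @return Named numeric vector of 14 metrics.
#' @export
asr_metrics <- function(events, habituation_mode = "conventional") {
  base <- events[events$block_id == "ASR_high20", , drop = FALSE]
  out <- event_summary_metrics(base, "asr")
  slc_freq <- function(e) if (nrow(e)) mean(e$label == "slc") else NA_real_
  f_base <- slc_freq(base)
  hab <- events[events$block_id == "ASR_hab", , drop = FALSE]
  hab_last <- utils::tail(hab[order(hab$stimulus_index), , drop = FALSE], 10)
  f_low <- slc_freq(events[events$block_id == "ASR_low", , drop = FALSE])
  f_med <- slc_freq(events[events$block_id == "ASR_med", , drop = FALSE])
  sens <- unname((f_low + f_med) / 2 + (f_med + f_base) / 2)
  c(
    out,
    asr_freq_slc = f_base,
    asr_freq_llc = if (nrow(base)) mean(base$label == "llc") else NA_real_,
    asr_sensitivity_index = sens,
    asr_ppi = habituation_ratio(
      slc_freq(events[events$block_id == "ASR_ppi4", , drop = FALSE]),
      f_base, habituation_mode
    ),
    asr_habituation = habituation_ratio(slc_freq(hab_last), f_base, habituation_mode)
  )
}

#' Assemble per-assay metric values into the full 94-metric vector
#'
#' @param parts Named list with any of `vmr`, `lf`, `df`, `asr`, each a
#'   named numeric vector as returned by the per-assay metric functions.
#' @param registry The [metric_registry()].
#' @return Named numeric vector with exactly one value (possibly `NA`) per
#'   registry id, in registry order.
#' @export
assemble_metric_vector <- function(parts, registry = metric_registry()) {
  all_vals <- unlist(unname(parts))
  if (anyDuplicated(names(all_vals))) {
    stop("duplicate metric ids: ", paste(names(all_vals)[duplicated(names(all_vals))], collapse = ", "))
  }
  unknown <- setdiff(names(all_vals), registry$id)
  if (length(unknown)) stop("unknown metric ids: ", paste(unknown, collapse = ", "))
  out <- stats::setNames(rep(NA_real_, nrow(registry)), registry$id)
  out[names(all_vals)] <- all_vals
  out
}

#' Compute the metric matrix for a whole cohort
#'
#' For a simulated cohort in `"events"` mode the latent response events and
#' bout records feed the metric formulas directly; in `"kinematic"` mode
#' responses are re-extracted from the per-frame trajectories with
#' [extract_assay_responses()] and VMR bouts re-detected with
#' [bouts_from_trajectory()], exercising the full kinematics path.
#'
#' @param cohort A `larva_cohort` from [simulate_cohort()], or a list with
#'   the same fields assembled from tracked data.
#' @param thresholds A [kinematic_thresholds()] object (kinematic mode).
#' @param registry The [metric_registry()].
#' @param habituation_mode `"conventional"` or `"literal"`; see
#'   [df_metrics()].
#' @param rim_fraction Outer-rim boundary as a fraction of well radius.
#' @return Data frame: `larva_id`, `genotype`, `treatment`, then one column
#'   per registry metric.
#' @export
compute_metric_matrix <- function(cohort, thresholds = kinematic_thresholds(),
                                  registry = metric_registry(),
                                  habituation_mode = "conventional",
                                  rim_fraction = 2 / 3) {
  ids <- cohort$genotypes$larva_id
  protocol <- cohort$protocol
  assays <- cohort$assays
  use_traj <- identical(cohort$mode, "kinematic")
  ev_by_larva <- if (!is.null(cohort$events)) split(cohort$events, cohort$events$larva_id)
  bouts_by_larva <- if (!is.null(cohort$vmr_bouts)) split(cohort$vmr_bouts, cohort$vmr_bouts$larva_id)
  pos_by_larva <- if (!is.null(cohort$vmr_positions)) split(cohort$vmr_positions, cohort$vmr_positions$larva_id)

  rows <- lapply(ids, function(id) {
    parts <- list()
    if ("VMR" %in% assays) {
      if (use_traj) {
        tr <- cohort$trajectories[[id]]
        tr <- tr[tr$assay == "VMR", , drop = FALSE]
        bouts <- bouts_from_trajectory(tr, thresholds)
        positions <- tr[, c("time_ms", "x", "y")]
      } else {
        bouts <- bouts_by_larva[[id]]
        if (is.null(bouts)) {
          bouts <- data.frame(
            start_ms = numeric(0), duration_ms = numeric(0),
            distance_px = numeric(0), displacement_px = numeric(0),
            mean_speed_px_ms = numeric(0)
          )
        }
        positions <- pos_by_larva[[id]]
      }
      parts$vmr <- vmr_metrics(bouts, positions, protocol,
        well_radius_px = cohort$well_radius_px %||% 45,
        rim_fraction = rim_fraction
      )
    }
    for (a in intersect(c("LF", "DF", "ASR"), assays)) {
      if (use_traj) {
        ev <- extract_assay_responses(cohort$trajectories[[id]], protocol, a, thresholds)
        des <- stimulus_design(protocol, a)[[a]]
        ev$train_index <- des$train_index
      } else {
        ev <- ev_by_larva[[id]]
        ev <- ev[ev$assay == a, , drop = FALSE]
      }
      parts[[tolower(a)]] <- switch(a,
        LF = event_summary_metrics(ev, "lf"),
        DF = df_metrics(ev, habituation_mode),
        ASR = asr_metrics(ev, habituation_mode)
      )
    }
    assemble_metric_vector(parts, registry)
  })
  mat <- do.call(rbind, rows)
  cbind(cohort$genotypes[, c("larva_id", "genotype", "treatment")],
    as.data.frame(mat),
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
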