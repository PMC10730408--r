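# Independent oracles used to freeze expected values. These deliberately
# use different formulations than the package implementation.

# Frame-by-frame state machine for bout finding: scans pairs directly
# instead of run-length encoding.
oracle_bouts <- function(d, thr = 0.7) {
  n <- length(d)
  starts <- integer(0)
  ends <- integer(0)
  in_bout <- FALSE
  start <- NA_integer_
  i <- 1L
  while (i <= n) {
    if (!in_bout) {
      if (i < n && d[i] > thr && d[i + 1] > thr) {
        in_bout <- TRUE
        start <- i
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    } else {
      if (i < n && d[i] <= thr && d[i + 1] <= thr) {
        starts <- c(starts, start)
        ends <- c(ends, i - 1L)
        in_bout <- FALSE
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
  }
  if (in_bout) {
    starts <- c(starts, start)
    ends <- c(ends, n)
  }
  data.frame(start_frame = starts, end_frame = ends)
}

# Unsigned angle between two 2D vectors via the dot product (the package
# uses atan2 of cross/dot).
oracle_angle <- function(a, b) {
  acos(min(max(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), -1), 1))
}

# Trapezoidal area under y at unit-spaced abscissae.
oracle_trapezoid <- function(y) {
  sum((y[-1] + y[-length(y)]) / 2)
}

# Textbook pooled-variance two-sample t.
oracle_pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# Independent classification decision table over (assay, curvature,
# latency), written as nested conditionals straight from the published
# rules.
oracle_classify <- function(assay, mc, lat, moved = TRUE) {
  if (!moved) {
    return("none")
  }
  if (assay %in% c("LF", "DF")) {
    if (lat <= 15) {
      return("too_early")
    }
    if (assay == "DF" && mc > 1.75) {
      return("obend")
    }
    if (mc > 0.5) {
      return("react")
    }
    return("none")
  }
  if (assay == "ASR") {
    if (mc > 0.8) {
      return(if (lat < 20) "slc" else "llc")
    }
    if (mc > 0.5) {
      return("react")
    }
    return("none")
  }
  stop("unknown assay")
}

# Small cohort used across tests.
tiny_cohort <- function(n = 8, seed = 42, mode = "events", assays = NULL, ...) {
  cfg <- cohort_config(n_larvae = n, seed = seed, ...)
  simulate_cohort(cfg, mode = mode, assays = assays)
}

# Deterministic response-event table for metric arithmetic tests.
fake_events <- function(assay, block_id, label, moved = NULL, train_index = NULL,
                        latency = 30, curv = 1, n = length(label)) {
  if (is.null(moved)) moved <- label != "none"
  data.frame(
    assay = rep_len(assay, n),
    block_id = rep_len(block_id, n),
    stimulus_index = seq_len(n),
    train_index = if (is.null(train_index)) rep_len(1L, n) else train_index,
    moved = rep_len(moved, n),
    label = rep_len(label, n),
    latency_ms = ifelse(rep_len(moved, n), rep_len(latency, n), NA_real_),
    max_curvature_rad = rep_len(curv, n),
    max_angular_velocity_rad_per_frame = rep_len(0.05, n),
    delta_orientation_rad = rep_len(1, n),
    displacement_px = rep_len(20, n),
    distance_px = rep_len(25, n),
    duration_ms = rep_len(60, n),
    stringsAsFactors = FALSE
  )
}
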