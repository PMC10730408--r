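# Synthetic cohort generator: genotype-dependent behavioral parameters,
# latent per-stimulus responses, spontaneous swim bouts, and (optionally)
# per-frame trajectories and rendered frames, with full ground truth.
#
# Two output modes share one generative model. "events" draws the latent
# per-stimulus response records and per-bout records directly; "kinematic"
# additionally integrates them into per-frame trajectories at the block
# frame rates, which the tracking-free kinematics path can then re-extract.

#' Behavioral parameters of one genotype group
#'
#' Defaults describe an unperturbed 6 dpf wild-type larva: dark-phase
#' locomotion above light-phase locomotion, a steep acoustic sensitivity
#' curve, strong short-latency startles at high intensity, and moderate
#' habituation and prepulse inhibition. Response probability within a
#' habituating train decays geometrically, `p_k = p * (1 - h)^(k - 1)`, and
#' resets between dark-flash blocks; a prepulse multiplies the response
#' probability by `1 - ppi_strength`. Latency and peak-curvature draws are
#' normal, clamped to the stated ranges; short-latency C-starts (SLC) stay
#' below 20 ms and long-latency C-starts (LLC) above it, so latency-based
#' classification can recover the latent class.
#'
#' @param bout_rate_per_min Spontaneous bout rate in the lit and dark VMR
#'   phases (bouts/min).
#' @param bout_duration_meanlog,bout_duration_sdlog,bout_duration_range_ms
#'   Log-normal bout duration (ms), clamped.
#' @param bout_speed_meanlog,bout_speed_sdlog Log-normal bout speed (px/ms).
#' @param bout_straightness Net displacement as a fraction of path length.
#' @param p_respond Baseline response probability per visual stimulus kind.
#' @param sensitivity_curve Acoustic response probability at the three
#'   ordinal intensity levels.
#' @param habituation_rate Per-stimulus multiplicative decay `h` in `[0, 1]`
#'   within a habituating train.
#' @param ppi_strength Fractional suppression in `[0, 1]` when a prepulse
#'   leads the pulse by 50 or 300 ms.
#' @param slc_fraction Probability that an acoustic response is SLC-like
#'   rather than LLC-like.
#' @param latency_params,curvature_params Per response class `c(mean, sd,
#'   min, max)` for latency (ms) and `c(mean, sd, min)` for peak curvature
#'   (rad).
#' @param response_kinematics Per response class `c(dur, dist, dori)`:
#'   movement duration (ms), path length (px), net orientation change (rad).
#' @param resting_curvature_rad Baseline body curvature of a still larva.
#' @param jitter_sd_px Sub-threshold centroid jitter in trajectories.
#' @param px_per_mm Pixel scale; classification thresholds are in px, so the
#'   scale only matters for well geometry and rendering.
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(bout_rate_per_min = c(light = 4, dark = 10),
                            bout_duration_meanlog = log(250),
                            bout_duration_sdlog = 0.25,
                            bout_duration_range_ms = c(150, 900),
                            bout_speed_meanlog = log(0.12),
                            bout_speed_sdlog = 0.3,
                            bout_straightness = 0.9,
                            p_respond = c(light_flash = 0.6, dark_flash = 0.8),
                            sensitivity_curve = c(low = 0.1, medium = 0.5, high = 0.85),
                            habituation_rate = 0.25,
                            ppi_strength = 0.4,
                            slc_fraction = 0.8,
                            latency_params = list(
                              slc = c(mean = 8, sd = 1.5, min = 4, max = 16),
                              llc = c(mean = 45, sd = 10, min = 24, max = 120),
                              obend = c(mean = 120, sd = 40, min = 25, max = 600),
                              react = c(mean = 60, sd = 20, min = 20, max = 300)
                            ),
                            curvature_params = list(
                              slc = c(mean = 1.7, sd = 0.25, min = 0.2),
                              llc = c(mean = 1.4, sd = 0.25, min = 0.2),
                              obend = c(mean = 2.4, sd = 0.3, min = 0.2),
                              react = c(mean = 1.1, sd = 0.3, min = 0.2)
                            ),
                            response_kinematics = list(
                              slc = c(dur = 40, dist = 40, dori = 1.2),
                              llc = c(dur = 50, dist = 35, dori = 1.0),
                              obend = c(dur = 100, dist = 60, dori = 1.8),
                              react = c(dur = 50, dist = 25, dori = 0.5)
                            ),
                            resting_curvature_rad = 0.1,
                            jitter_sd_px = 0.05,
                            px_per_mm = 10) {
  probs <- c(p_respond, sensitivity_curve, habituation_rate, ppi_strength, slc_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(bout_rate_per_min < 0)) stop("bout rates must be >= 0")
  if (latency_params$slc[["mean"]] >= 20 || latency_params$llc[["mean"]] <= 20) {
    stop("SLC latency mean must be < 20 ms and LLC latency mean > 20 ms")
  }
  p <- as.list(environment())
  class(p) <- "behavior_params"
  p
}

#' Cohort configuration
#'
#' @param n_larvae Number of larvae in the behavioral run (the published
#'   screen uses approximately 50 per mutant allele).
#' @param genotype_proportions Named proportions over genotype groups; the
#'   default is the Mendelian 1:2:1 of a heterozygote incross.
#' @param params Named list of [behavior_params()] per genotype; groups not
#'   listed inherit the first entry.
#' @param treatment Treatment label carried into the genotype table.
#' @param seed Integer seed; mandatory for reproducible simulation.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_larvae = 50,
                          genotype_proportions = c(wt = 0.25, het = 0.5, mut = 0.25),
                          params = list(wt = behavior_params()),
                          treatment = "E3",
                          seed = 1L) {
  if (n_larvae < 1) stop("n_larvae must be >= 1")
  if (abs(sum(genotype_proportions) - 1) > 1e-8) {
    stop("genotype proportions must sum to 1")
  }
  if (is.null(names(genotype_proportions))) stop("genotype proportions must be named")
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  for (g in setdiff(names(genotype_proportions), names(params))) {
    params[[g]] <- params[[1]]
  }
  structure(
    list(
      n_larvae = as.integer(n_larvae),
      genotype_proportions = genotype_proportions,
      params = params,
      treatment = treatment,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

rnorm_clamped <- function(n, mean, sd, min = -Inf, max = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), min), max)
}

# Design table of recorded stimuli with habituation train indices.
stimulus_design <- function(protocol, assays) {
  out <- list()
  if ("LF" %in% assays && "LF" %in% names(protocol$blocks)) {
    ev <- events_of(protocol, "LF", function(e) e$recorded & e$kind == "light_flash")
    ev$assay <- "LF"
    ev$train_index <- 1L
    out$LF <- ev
  }
  if ("DF" %in% assays && "DF" %in% names(protocol$blocks)) {
    ev <- events_of(protocol, "DF", function(e) e$recorded & e$kind == "dark_flash")
    ev$assay <- "DF"
    ev$train_index <- as.integer(stats::ave(
      seq_len(nrow(ev)), ev$block_id, FUN = seq_along
    ))
    out$DF <- ev
  }
  if ("ASR" %in% assays && "ASR" %in% names(protocol$blocks)) {
    ev <- events_of(protocol, "ASR", function(e) e$recorded & e$kind == "acoustic")
    ev$assay <- "ASR"
    ev$train_index <- 1L
    hab <- ev$block_id == "ASR_hab"
    ev$train_index[hab] <- seq_len(sum(hab))
    out$ASR <- ev
  }
  out
}

# Latent response probability for one genotype's params over a design table.
response_probability <- function(design, p) {
  h <- p$habituation_rate
  base <- numeric(nrow(design))
  vis <- design$kind %in% c("light_flash", "dark_flash")
  base[vis] <- p$p_respond[design$kind[vis]]
  ac <- design$kind == "acoustic"
  base[ac] <- p$sensitivity_curve[design$intensity[ac]]
  decay <- (1 - h)^(design$train_index - 1)
  pp <- ifelse(is.na(design$prepulse_intensity), 1, 1 - p$ppi_strength)
  base * decay * pp
}

draw_response_events <- function(larva_ids, genotype, p, design) {
  n_l <- length(larva_ids)
  n_s <- nrow(design)
  n <- n_l * n_s
  d <- design[rep(seq_len(n_s), times = n_l), , drop = FALSE]
  d$larva_id <- rep(larva_ids, each = n_s)
  d$genotype <- genotype
  d$p_respond_latent <- rep(response_probability(design, p), times = n_l)
  d$responded <- stats::runif(n) < d$p_respond_latent

  cls <- rep(NA_character_, n)
  vis <- d$kind == "dark_flash"
  cls[d$responded & vis] <- "obend"
  cls[d$responded & d$kind == "light_flash"] <- "react"
  ac <- d$responded & d$kind == "acoustic"
  cls[ac] <- ifelse(stats::runif(sum(ac)) < p$slc_fraction, "slc", "llc")
  d$latent_class <- cls

  d$latency_ms <- NA_real_
  d$max_curvature_rad <- p$resting_curvature_rad
  d$duration_ms <- NA_real_
  d$distance_px <- NA_real_
  d$displacement_px <- NA_real_
  d$delta_orientation_rad <- NA_real_
  d$max_angular_velocity_rad_per_frame <- NA_real_
  d$bend_sign <- NA_real_
  for (k in c("slc", "llc", "obend", "react")) {
    i <- which(cls == k)
    if (!length(i)) next
    lp <- p$latency_params[[k]]
    cp <- p$curvature_params[[k]]
    rk <- p$response_kinematics[[k]]
    d$latency_ms[i] <- rnorm_clamped(length(i), lp[["mean"]], lp[["sd"]], lp[["min"]], lp[["max"]])
    d$max_curvature_rad[i] <- rnorm_clamped(length(i), cp[["mean"]], cp[["sd"]], cp[["min"]])
    d$duration_ms[i] <- rnorm_clamped(length(i), rk[["dur"]], 0.15 * rk[["dur"]], 20)
    # keep path speed above ~0.45 px/ms so movement onset is always
    # detectable against the 0.7 px/frame bout criterion at 500 fps
    d$distance_px[i] <- pmax(
      rnorm_clamped(length(i), rk[["dist"]], 0.25 * rk[["dist"]], 2),
      0.45 * d$duration_ms[i]
    )
    d$displacement_px[i] <- p$bout_straightness * d$distance_px[i]
    d$delta_orientation_rad[i] <- rnorm_clamped(length(i), rk[["dori"]], 0.3 * rk[["dori"]], 0.05, pi)
    d$bend_sign[i] <- sample(c(-1, 1), length(i), replace = TRUE)
  }
  moved <- d$responded
  # peak per-frame orientation change of the linear ramp at 500 fps
  d$max_angular_velocity_rad_per_frame <- d$delta_orientation_rad * 2 / d$duration_ms
  d$moved <- moved
  d
}

# Spontaneous VMR bouts and well positions for one larva. Each bout moves
# the larva by its net displacement (capped so one bout cannot overshoot
# the well) in a random direction, with radial reflection at the wall.
draw_vmr_latents <- function(p, phases, well_radius_px) {
  bouts <- list()
  for (ph in c("light", "dark")) {
    span <- phases[[ph]]
    rate <- p$bout_rate_per_min[[ph]]
    n <- stats::rpois(1, rate * span$duration / 60000)
    starts <- sort(stats::runif(n, span$start, span$start + span$duration - 1000))
    dur <- pmin(pmax(
      stats::rlnorm(n, p$bout_duration_meanlog, p$bout_duration_sdlog),
      p$bout_duration_range_ms[1]
    ), p$bout_duration_range_ms[2])
    # a bout may not start before the previous one has ended plus two
    # frames at 20 fps
    keep <- rep(TRUE, n)
    if (n > 1) {
      last_end <- starts[1] + dur[1]
      for (i in seq_len(n)[-1]) {
        if (starts[i] < last_end + 100) {
          keep[i] <- FALSE
        } else {
          last_end <- starts[i] + dur[i]
        }
      }
    }
    starts <- starts[keep]
    dur <- dur[keep]
    n <- length(starts)
    speed <- stats::rlnorm(n, p$bout_speed_meanlog, p$bout_speed_sdlog)
    dist <- speed * dur
    bouts[[ph]] <- data.frame(
      phase = rep(ph, n),
      start_ms = starts, duration_ms = dur,
      distance_px = dist,
      displacement_px = p$bout_straightness * dist,
      mean_speed_px_ms = speed
    )
  }
  bouts <- do.call(rbind, bouts)
  bouts <- bouts[order(bouts$start_ms), , drop = FALSE]
  n <- nrow(bouts)

  r0 <- well_radius_px * sqrt(stats::runif(1))
  phi0 <- stats::runif(1, 0, 2 * pi)
  cur <- c(r0 * cos(phi0), r0 * sin(phi0))
  psi <- stats::runif(n, 0, 2 * pi)
  step_len <- pmin(bouts$displacement_px, 0.85 * well_radius_px)
  px <- numeric(n)
  py <- numeric(n)
  for (i in seq_len(n)) {
    cand <- cur + step_len[i] * c(cos(psi[i]), sin(psi[i]))
    r <- sqrt(sum(cand^2))
    if (r > well_radius_px) cand <- cand * (2 * well_radius_px - r) / r
    cur <- cand
    px[i] <- cand[1]
    py[i] <- cand[2]
  }
  positions <- data.frame(
    time_ms = c(phases$light$start, bouts$start_ms + bouts$duration_ms),
    x = c(r0 * cos(phi0), px),
    y = c(r0 * sin(phi0), py)
  )
  list(bouts = bouts, positions = positions)
}

#' Simulate a behavioral cohort
#'
#' Draws genotypes, latent per-stimulus responses (Bernoulli with
#' habituation and prepulse modulation), latent response kinematics, and
#' spontaneous VMR bouts for every larva, under the per-genotype
#' [behavior_params()]. In `"kinematic"` mode the latents are additionally
#' integrated into per-frame trajectories over every recorded segment at
#' the block frame rates (20 fps VMR, 500 fps otherwise), with positions
#' confined to a 9 mm circular well. With a fixed seed the output is
#' bit-for-bit reproducible.
#'
#' @param config A [cohort_config()].
#' @param protocol A `protocol`; defaults to [build_default_protocol()].
#' @param mode `"events"` (latent records only; fast) or `"kinematic"`
#'   (also per-frame trajectories).
#' @param assays Subset of assays to simulate (default: all in the
#'   protocol).
#' @return A `larva_cohort` list: `genotypes` (larva_id, well_id, genotype,
#'   treatment), `events` (ground-truth-annotated response events with
#'   classification labels), `vmr_bouts`, `vmr_positions` (piecewise-
#'   constant well positions), `trajectories` (kinematic mode only: one
#'   data frame per larva), plus `protocol`, `config`, `mode`.
#' @export
simulate_cohort <- function(config, protocol = build_default_protocol(),
                            mode = c("events", "kinematic"),
                            assays = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  mode <- match.arg(mode)
  if (is.null(assays)) assays <- names(protocol$blocks)
  set.seed(config$seed)

  n <- config$n_larvae
  geno_levels <- names(config$genotype_proportions)
  genotype <- sample(geno_levels, n, replace = TRUE, prob = config$genotype_proportions)
  genotypes <- data.frame(
    larva_id = sprintf("L%03d", seq_len(n)),
    well_id = seq_len(n),
    genotype = genotype,
    treatment = config$treatment,
    stringsAsFactors = FALSE
  )

  design <- stimulus_design(protocol, assays)
  design_all <- if (length(design)) do.call(rbind, design) else NULL
  well_radius <- 4.5 * config$params[[1]]$px_per_mm

  events <- NULL
  vmr_bouts <- NULL
  vmr_positions <- NULL
  for (g in geno_levels) {
    ids <- genotypes$larva_id[genotypes$genotype == g]
    if (!length(ids)) next
    p <- config$params[[g]]
    if (!is.null(design_all)) {
      ev <- draw_response_events(ids, g, p, design_all)
      events <- rbind(events, ev)
    }
    if ("VMR" %in% assays && "VMR" %in% names(protocol$blocks)) {
      phases <- vmr_phases(protocol)
      for (id in ids) {
        lat <- draw_vmr_latents(p, phases, well_radius)
        if (nrow(lat$bouts)) lat$bouts <- cbind(larva_id = id, lat$bouts)
        lat$positions <- cbind(larva_id = id, lat$positions)
        vmr_bouts <- rbind(vmr_bouts, lat$bouts)
        vmr_positions <- rbind(vmr_positions, lat$positions)
      }
    }
  }
  if (!is.null(events)) {
    events <- events[order(events$larva_id, events$assay, events$stimulus_index), ]
    rownames(events) <- NULL
    events$label <- classify_response(
      events$assay, events$max_curvature_rad, events$latency_ms, events$moved
    )
  }

  cohort <- structure(
    list(
      genotypes = genotypes,
      events = events,
      vmr_bouts = vmr_bouts,
      vmr_positions = vmr_positions,
      trajectories = NULL,
      protocol = protocol,
      assays = assays,
      config = config,
      mode = mode,
      well_radius_px = well_radius
    ),
    class = "larva_cohort"
  )
  if (mode == "kinematic") {
    cohort$trajectories <- build_trajectories(cohort)
  }
  cohort
}

#' @export
print.larva_cohort <- function(x, ...) {
  cat(
    "<larva_cohort> ", nrow(x$genotypes), " larvae (",
    paste(names(table(x$genotypes$genotype)), table(x$genotypes$genotype),
      sep = ":", collapse = ", "
    ),
    "), mode ", x$mode, "\n",
    sep = ""
  )
  invisible(x)
}

# Integrate latent records into per-frame trajectories.
build_trajectories <- function(cohort) {
  protocol <- cohort$protocol
  out <- list()
  for (i in seq_len(nrow(cohort$genotypes))) {
    id <- cohort$genotypes$larva_id[i]
    p <- cohort$config$params[[cohort$genotypes$genotype[i]]]
    segs <- list()
    if ("VMR" %in% cohort$assays && !is.null(cohort$vmr_positions)) {
      segs$VMR <- vmr_trajectory(cohort, id, p)
    }
    for (a in intersect(c("LF", "DF", "ASR"), cohort$assays)) {
      segs[[a]] <- response_trajectory(cohort, id, a, p)
    }
    traj <- do.call(rbind, segs)
    rownames(traj) <- NULL
    out[[id]] <- traj
  }
  out
}

vmr_trajectory <- function(cohort, id, p) {
  phases <- vmr_phases(cohort$protocol)
  fps <- cohort$protocol$blocks$VMR$frame_rate_fps
  dt <- 1000 / fps
  t0 <- phases$light$start
  t_end <- phases$dark$start + phases$dark$duration
  ft <- seq(t0, t_end - dt, by = dt)

  pos <- cohort$vmr_positions[cohort$vmr_positions$larva_id == id, , drop = FALSE]
  b <- cohort$vmr_bouts
  b <- if (is.null(b)) NULL else b[b$larva_id == id, , drop = FALSE]
  nb <- if (is.null(b)) 0L else nrow(b)
  if (nb) {
    # knots: stationary between bouts, linear motion within a bout
    kt <- c(t0, as.vector(rbind(b$start_ms, b$start_ms + b$duration_ms)))
    kx <- c(pos$x[1], as.vector(rbind(pos$x[-nrow(pos)], pos$x[-1])))
    ky <- c(pos$y[1], as.vector(rbind(pos$y[-nrow(pos)], pos$y[-1])))
    x <- stats::approx(kt, kx, xout = ft, rule = 2)$y
    y <- stats::approx(kt, ky, xout = ft, rule = 2)$y
  } else {
    x <- rep(pos$x[1], length(ft))
    y <- rep(pos$y[1], length(ft))
  }
  nf <- length(ft)
  data.frame(
    larva_id = id, assay = "VMR", block_id = "VMR",
    stimulus_index = NA_integer_, frame = seq_len(nf), time_ms = ft,
    x = x + stats::rnorm(nf, 0, p$jitter_sd_px),
    y = y + stats::rnorm(nf, 0, p$jitter_sd_px),
    curvature_rad = p$resting_curvature_rad + abs(stats::rnorm(nf, 0, 0.02)),
    orientation_rad = 0,
    stringsAsFactors = FALSE
  )
}

response_trajectory <- function(cohort, id, assay, p) {
  block <- cohort$protocol$blocks[[assay]]
  dt <- 1000 / block$frame_rate_fps
  ev <- cohort$events[cohort$events$larva_id == id & cohort$events$assay == assay, , drop = FALSE]
  if (!nrow(ev)) return(NULL)
  window <- block$record_window_ms
  t_rel <- seq(0, window, by = dt)
  nf <- length(t_rel)
  segs <- vector("list", nrow(ev))
  x0 <- stats::runif(nrow(ev), -10, 10)
  y0 <- stats::runif(nrow(ev), -10, 10)
  ori0 <- stats::runif(nrow(ev), -pi, pi)
  for (j in seq_len(nrow(ev))) {
    e <- ev[j, ]
    x <- rep(x0[j], nf)
    y <- rep(y0[j], nf)
    curv <- p$resting_curvature_rad + abs(stats::rnorm(nf, 0, 0.02))
    ori <- rep(ori0[j], nf)
    if (isTRUE(e$responded)) {
      lat <- e$latency_ms
      dur <- e$duration_ms
      u <- (t_rel - lat) / dur
      # two-leg constant-speed path: total path length = distance_px, net
      # chord = displacement_px
      ratio <- min(e$displacement_px / e$distance_px, 1)
      alpha <- acos(pmin(pmax(2 * ratio^2 - 1, -1), 1))
      half <- e$distance_px / 2
      th1 <- stats::runif(1, 0, 2 * pi)
      th2 <- th1 + e$bend_sign * alpha
      leg1 <- c(cos(th1), sin(th1)) * half
      leg2 <- c(cos(th2), sin(th2)) * half
      s <- pmin(pmax(u, 0), 1) # fraction of movement completed
      d1 <- pmin(s, 0.5) * 2
      d2 <- pmax(s - 0.5, 0) * 2
      x <- x0[j] + d1 * leg1[1] + d2 * leg2[1]
      y <- y0[j] + d1 * leg1[2] + d2 * leg2[2]
      inpulse <- u >= 0 & u <= 1
      curv[inpulse] <- curv[inpulse] +
        (e$max_curvature_rad - p$resting_curvature_rad) *
          0.5 * (1 - cos(2 * pi * u[inpulse]))
      ori <- ori0[j] + e$bend_sign * e$delta_orientation_rad * s
    }
    segs[[j]] <- data.frame(
      larva_id = id, assay = assay, block_id = e$block_id,
      stimulus_index = e$stimulus_index, frame = seq_len(nf),
      time_ms = e$onset_ms + t_rel,
      x = x + stats::rnorm(nf, 0, p$jitter_sd_px),
      y = y + stats::rnorm(nf, 0, p$jitter_sd_px),
      curvature_rad = curv,
      orientation_rad = ori,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, segs)
}

#' Render grayscale frames from poses
#'
#' Draws a bright larva on a dark background: a head blob, a short straight
#' rostral body section, and a tapered tail laid along a constant-curvature
#' arc whose five vertices are the ground-truth tail points. The whole body
#' is translated so that its intensity center of mass lands on the pose
#' centroid, which is the quantity a centroid tracker estimates.
#'
#' @param poses Data frame with columns `x`, `y`, `orientation_rad`,
#'   `curvature_rad` and optionally `bend_sign` (one frame per row); zero
#'   rows renders empty frames.
#' @param image_size `c(rows, cols)`.
#' @param noise_sd Additive Gaussian pixel noise.
#' @param step_px Tail segment length (px).
#' @return List with `frames` (list of matrices), `background` (matrix) and
#'   `truth` (poses plus ground-truth tail point coordinates).
#' @export
render_frames <- function(poses, image_size = c(96, 96), noise_sd = 0,
                          step_px = 6.5) {
  bg_level <- 8
  background <- matrix(bg_level, image_size[1], image_size[2])
  n_pose <- nrow(poses)
  if (is.null(poses$bend_sign)) poses$bend_sign <- rep(1, n_pose)
  frames <- vector("list", max(n_pose, 0))
  truth <- poses
  for (k in c(paste0("tail_x", 1:5), paste0("tail_y", 1:5))) {
    truth[[k]] <- rep(NA_real_, n_pose)
  }

  for (f in seq_len(n_pose)) {
    ori <- poses$orientation_rad[f]
    kappa <- poses$curvature_rad[f]
    s <- poses$bend_sign[f]
    # local body geometry, bend start at the origin
    rostral_len <- 12
    u_rost <- c(cos(ori), sin(ori))
    rost_s <- seq(1, rostral_len, by = 1)
    rost_pts <- cbind(rost_s * u_rost[1], rost_s * u_rost[2])
    head_c <- (rostral_len + 4) * u_rost
    # tail vertices: five segments, uniform direction increments kappa/4
    phis <- ori + pi + s * kappa * (0:4) / 4
    vx <- cumsum(step_px * cos(phis))
    vy <- cumsum(step_px * sin(phis))
    verts <- cbind(c(0, vx), c(0, vy))
    # dense splats along the tail polyline, 1 px apart, tapering amplitude
    tail_pts <- NULL
    for (i in 1:5) {
      tt <- seq(0, 1, length.out = ceiling(step_px) + 1)[-1]
      tail_pts <- rbind(
        tail_pts,
        cbind(
          verts[i, 1] + tt * (verts[i + 1, 1] - verts[i, 1]),
          verts[i, 2] + tt * (verts[i + 1, 2] - verts[i, 2])
        )
      )
    }
    n_tail <- nrow(tail_pts)
    splat_x <- c(head_c[1], rost_pts[, 1], tail_pts[, 1])
    splat_y <- c(head_c[2], rost_pts[, 2], tail_pts[, 2])
    splat_a <- c(240, rep(120, nrow(rost_pts)), seq(120, 40, length.out = n_tail))
    splat_s <- c(3.0, rep(1.0, nrow(rost_pts)), rep(1.0, n_tail))
    mass <- splat_a * splat_s^2
    mx <- sum(mass * splat_x) / sum(mass)
    my <- sum(mass * splat_y) / sum(mass)
    shift_x <- poses$x[f] - mx
    shift_y <- poses$y[f] - my
    splat_x <- splat_x + shift_x
    splat_y <- splat_y + shift_y
    truth[f, paste0("tail_x", 1:5)] <- verts[-1, 1] + shift_x
    truth[f, paste0("tail_y", 1:5)] <- verts[-1, 2] + shift_y

    lim <- 3 * max(splat_s)
    if (any(splat_x < lim) || any(splat_y < lim) ||
      any(splat_x > image_size[2] - 1 - lim) || any(splat_y > image_size[1] - 1 - lim)) {
      stop("posture outside frame bounds")
    }
    img <- background
    for (i in seq_along(splat_x)) {
      r <- ceiling(3 * splat_s[i])
      rows <- (round(splat_y[i]) - r):(round(splat_y[i]) + r) + 1
      cols <- (round(splat_x[i]) - r):(round(splat_x[i]) + r) + 1
      yy <- (rows - 1) - splat_y[i]
      xx <- (cols - 1) - splat_x[i]
      g <- splat_a[i] * exp(-(outer(yy^2, xx^2, "+")) / (2 * splat_s[i]^2))
      img[rows, cols] <- img[rows, cols] + g
    }
    img <- pmin(img, 255)
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), nrow(img))
    }
    frames[[f]] <- img
  }
  if (n_pose == 0) {
    frames <- list(background +
      if (noise_sd > 0) matrix(stats::rnorm(length(background), 0, noise_sd), nrow(background)) else 0)
  }
  list(frames = frames, background = background, truth = truth)
}

#' Compare estimated metrics against generating parameters
#'
#' For each genotype group, contrasts the cohort-mean habituation, prepulse
#' inhibition, response-frequency and bout-count estimates against their
#' closed-form expectations under the generating [behavior_params()].
#'
#' @param metrics Metric matrix from [compute_metric_matrix()].
#' @param cohort The `larva_cohort` the metrics were computed from.
#' @return Data frame with columns `genotype`, `parameter`, `expected`,
#'   `estimated`, `bias`, `n`.
#' @export
recover_parameters <- function(metrics, cohort) {
  protocol <- cohort$protocol
  out <- list()
  for (g in unique(cohort$genotypes$genotype)) {
    p <- cohort$config$params[[g]]
    m <- metrics[metrics$genotype == g, , drop = FALSE]
    n_g <- nrow(m)
    est <- function(col) mean(m[[col]], na.rm = TRUE)
    h <- p$habituation_rate

    rows <- list()
    if ("asr_ppi" %in% names(m)) {
      rows$ppi <- c(expected = p$ppi_strength, estimated = est("asr_ppi"))
      rows$habituation_asr <- c(
        expected = 1 - mean((1 - h)^(20:29)),
        estimated = est("asr_habituation")
      )
      cp <- p$curvature_params$slc
      p_slc <- p$sensitivity_curve[["high"]] * p$slc_fraction *
        stats::pnorm(0.8, cp[["mean"]], cp[["sd"]], lower.tail = FALSE)
      rows$slc_frequency <- c(expected = unname(p_slc), estimated = est("asr_freq_slc"))
    }
    if ("df_freq_obend" %in% names(m)) {
      design <- stimulus_design(protocol, "DF")$DF
      cp <- p$curvature_params$obend
      p_ob <- mean(p$p_respond[["dark_flash"]] * (1 - h)^(design$train_index - 1)) *
        stats::pnorm(1.75, cp[["mean"]], cp[["sd"]], lower.tail = FALSE)
      rows$obend_frequency <- c(expected = unname(p_ob), estimated = est("df_freq_obend"))
    }
    if ("lf_freq_react" %in% names(m)) {
      cp <- p$curvature_params$react
      p_re <- p$p_respond[["light_flash"]] *
        stats::pnorm(0.5, cp[["mean"]], cp[["sd"]], lower.tail = FALSE)
      rows$lf_react_frequency <- c(expected = unname(p_re), estimated = est("lf_freq_react"))
    }
    if ("vmr_light_on_full_n_bouts" %in% names(m)) {
      phases <- vmr_phases(protocol)
      # Poisson seeds thinned by the refractory rule: a candidate falling
      # within a running bout plus two frames is discarded, so the
      # effective rate is r / (1 + r * tau) with tau the mean busy span.
      tau_ms <- exp(p$bout_duration_meanlog + p$bout_duration_sdlog^2 / 2) + 100
      thinned <- function(rate_min, dur_ms) {
        r <- rate_min / 60000
        (r / (1 + r * tau_ms)) * dur_ms
      }
      rows$bouts_light <- c(
        expected = thinned(p$bout_rate_per_min[["light"]], phases$light$duration),
        estimated = est("vmr_light_on_full_n_bouts")
      )
      rows$bouts_dark <- c(
        expected = thinned(p$bout_rate_per_min[["dark"]], phases$dark$duration),
        estimated = est("vmr_light_off_full_n_bouts")
      )
    }
    if (length(rows)) {
      df <- data.frame(
        genotype = g,
        parameter = names(rows),
        expected = vapply(rows, `[[`, numeric(1), "expected"),
        estimated = vapply(rows, `[[`, numeric(1), "estimated"),
        n = n_g,
        stringsAsFactors = FALSE
      )
      df$bias <- df$estimated - df$expected
      out[[g]] <- df
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
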