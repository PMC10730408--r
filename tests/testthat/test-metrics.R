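test_that("the registry partitions 94 metrics as 60/9/11/14", {
  reg <- metric_registry()
  expect_equal(nrow(reg), 94)
  expect_false(anyDuplicated(reg$id) > 0)
  counts <- table(reg$assay)
  expect_equal(as.integer(counts[c("VMR", "LF", "DF", "ASR")]), c(60L, 9L, 11L, 14L))
  expect_equal(sum(reg$assay == "VMR" & grepl("first_min", reg$bin)), 20)
})

test_that("VMR metrics follow the arithmetic contract in each bin", {
  p <- build_default_protocol()
  # two bouts in the first lit minute: distances 10 and 20 px
  bouts <- data.frame(
    start_ms = c(600500, 610000, 1085000),
    duration_ms = c(200, 400, 300),
    distance_px = c(10, 20, 12),
    displacement_px = c(8, 15, 10),
    mean_speed_px_ms = c(0.05, 0.05, 0.04)
  )
  positions <- data.frame(time_ms = 600000, x = 0, y = 0) # pinned at center
  v <- vmr_metrics(bouts, positions, p)
  expect_equal(unname(v["vmr_light_on_first_min_n_bouts"]), 2)
  expect_equal(unname(v["vmr_light_on_first_min_total_distance_px"]), 30)
  expect_equal(unname(v["vmr_light_on_first_min_avg_bout_distance_px"]), 15)
  expect_equal(unname(v["vmr_light_on_first_min_avg_speed_px_ms"]), 30 / 600)
  expect_equal(unname(v["vmr_light_off_full_n_bouts"]), 1)
  # empty bin: zero counts/totals, missing per-bout averages
  expect_equal(unname(v["vmr_light_off_last_min_n_bouts"]), 0)
  expect_equal(unname(v["vmr_light_off_last_min_total_distance_px"]), 0)
  expect_true(is.na(v["vmr_light_off_last_min_avg_bout_time_ms"]))
  # pinned at the well center
  expect_equal(unname(v["vmr_light_on_full_avg_dist_center_px"]), 0)
  expect_equal(unname(v["vmr_light_on_full_frac_time_outer_rim"]), 0)

  # position in the outer rim the whole time
  rim <- data.frame(time_ms = 600000, x = 40, y = 0)
  v2 <- vmr_metrics(bouts, rim, p)
  expect_equal(unname(v2["vmr_light_off_full_frac_time_outer_rim"]), 1)
  expect_equal(unname(v2["vmr_light_off_full_avg_dist_center_px"]), 40)
})

test_that("bouts straddling a bin boundary count toward their start bin", {
  p <- build_default_protocol()
  # starts in the last lit minute, ends after lights-off begins
  bouts <- data.frame(
    start_ms = 1079900, duration_ms = 400, distance_px = 10,
    displacement_px = 8, mean_speed_px_ms = 0.025
  )
  positions <- data.frame(time_ms = 600000, x = 0, y = 0)
  v <- vmr_metrics(bouts, positions, p)
  expect_equal(unname(v["vmr_light_on_last_min_n_bouts"]), 1)
  expect_equal(unname(v["vmr_light_off_first_min_n_bouts"]), 0)
})

test_that("event summaries report frequencies and gated feature means", {
  ev <- fake_events("LF", "LF", c(rep("react", 12), rep("none", 3)),
    moved = c(rep(TRUE, 12), rep(FALSE, 3)), latency = 30
  )
  s <- event_summary_metrics(ev, "lf")
  expect_equal(unname(s["lf_freq_react"]), 0.8)
  expect_equal(unname(s["lf_freq_no_movement"]), 0.2)
  expect_equal(unname(s["lf_avg_latency_ms"]), 30)

  none <- fake_events("LF", "LF", rep("none", 15), moved = FALSE)
  s0 <- event_summary_metrics(none, "lf")
  expect_equal(unname(s0["lf_freq_no_movement"]), 1)
  expect_equal(unname(s0["lf_freq_react"]), 0)
  expect_true(all(is.na(s0[grep("avg", names(s0))])))

  expect_error(event_summary_metrics(fake_events("LF", "LF", character(0)), "lf"),
    "no stimuli")
})

test_that("dark-flash habituation follows first-versus-last block frequencies", {
  labels <- c(
    ifelse(seq_len(14) <= 11, "obend", "react"), # block 1: 11/14 obends
    rep("react", 14), # block 3
    ifelse(seq_len(14) <= 4, "obend", "react") # block 5: 4/14
  )
  ev <- fake_events("DF", rep(c("DF1", "DF3", "DF5"), each = 14), labels,
    latency = 60, curv = 2
  )
  d <- df_metrics(ev)
  expect_equal(unname(d["df_freq_obend"]), 15 / 42)
  expect_equal(unname(d["df_habituation"]), 1 - (4 / 14) / (11 / 14))

  # complete habituation and no habituation
  full <- fake_events("DF", rep(c("DF1", "DF3", "DF5"), each = 14),
    c(rep("obend", 14), rep("obend", 14), rep("react", 14)),
    latency = 60, curv = 2
  )
  expect_equal(unname(df_metrics(full)["df_habituation"]), 1)
  flat <- fake_events("DF", rep(c("DF1", "DF3", "DF5"), each = 14),
    rep(c("obend", "react"), 21), latency = 60, curv = 2
  )
  expect_equal(unname(df_metrics(flat)["df_habituation"]), 0)

  # undefined when the first block has no O-bends
  noneearly <- fake_events("DF", rep(c("DF1", "DF3", "DF5"), each = 14),
    c(rep("react", 28), rep("obend", 14)), latency = 60, curv = 2
  )
  expect_true(is.na(df_metrics(noneearly)["df_habituation"]))

  # literal published form: (1 - late) / early
  lit <- df_metrics(ev, habituation_mode = "literal")
  expect_equal(unname(lit["df_habituation"]), (1 - 4 / 14) / (11 / 14))
})

test_that("startle metrics compute PPI, habituation and the sensitivity index", {
  mk_asr <- function(slc_low, slc_med, slc_base, slc_ppi4, slc_hab_last) {
    blocks <- c(
      rep("ASR_low", 10), rep("ASR_med", 10),
      rep(c("ASR_ppi1", "ASR_ppi2", "ASR_ppi3", "ASR_ppi4", "ASR_high20"), 10),
      rep("ASR_hab", 30)
    )
    lab <- rep("none", length(blocks))
    assign_n <- function(lab, block, k, value) {
      idx <- which(blocks == block)
      lab[idx[seq_len(k)]] <- value
      lab
    }
    lab <- assign_n(lab, "ASR_low", round(10 * slc_low), "slc")
    lab <- assign_n(lab, "ASR_med", round(10 * slc_med), "slc")
    lab <- assign_n(lab, "ASR_high20", round(10 * slc_base), "slc")
    lab <- assign_n(lab, "ASR_ppi4", round(10 * slc_ppi4), "slc")
    hab_idx <- which(blocks == "ASR_hab")
    lab[hab_idx[20 + seq_len(round(10 * slc_hab_last))]] <- "slc"
    ev <- fake_events("ASR", blocks, lab,
      moved = lab == "slc", latency = 10, curv = 1.5
    )
    ev$train_index <- 1L
    ev$train_index[blocks == "ASR_hab"] <- 1:30
    ev
  }
  ev <- mk_asr(0, 0.5, 1.0, 0.2, 0.3)
  a <- asr_metrics(ev)
  expect_equal(unname(a["asr_sensitivity_index"]), oracle_trapezoid(c(0, 0.5, 1.0)))
  expect_equal(unname(a["asr_sensitivity_index"]), 1.0)
  expect_equal(unname(a["asr_ppi"]), 1 - 0.2 / 1.0)
  expect_equal(unname(a["asr_habituation"]), 1 - 0.3 / 1.0)
  expect_equal(unname(a["asr_freq_slc"]), 1.0)

  # PPI4 0.2 against baseline 0.8
  a2 <- asr_metrics(mk_asr(0.1, 0.4, 0.8, 0.2, 0.8))
  expect_equal(unname(a2["asr_ppi"]), 0.75)
  expect_equal(unname(a2["asr_habituation"]), 0) # last-10 equals baseline

  # undefined when baseline SLC frequency is zero
  a3 <- asr_metrics(mk_asr(0, 0, 0, 0, 0.3))
  expect_true(is.na(a3["asr_ppi"]))
  expect_true(is.na(a3["asr_habituation"]))

  # sensitivity index is monotone in each per-intensity frequency
  base <- c(0.2, 0.5, 0.7)
  s0 <- oracle_trapezoid(base)
  for (i in 1:3) {
    up <- base
    up[i] <- up[i] + 0.2
    expect_gte(oracle_trapezoid(up), s0)
    inc <- mk_asr(up[1], up[2], up[3], 0.2, 0.3)
    expect_gte(unname(asr_metrics(inc)["asr_sensitivity_index"]), s0)
  }
})

test_that("metric vectors assemble against the registry", {
  reg <- metric_registry()
  co <- tiny_cohort(n = 2, seed = 77)
  m <- compute_metric_matrix(co)
  expect_equal(ncol(m), 3 + 94)
  expect_identical(names(m)[-(1:3)], reg$id)

  # VMR only: 60 filled, 34 missing
  co_v <- tiny_cohort(n = 2, seed = 78, assays = "VMR")
  m_v <- compute_metric_matrix(co_v)
  vals <- unlist(m_v[1, reg$id])
  expect_equal(sum(is.na(vals[reg$id[reg$assay != "VMR"]])), 34)

  # empty input: all missing, length 94
  empty <- assemble_metric_vector(list())
  expect_length(empty, 94)
  expect_true(all(is.na(empty)))

  expect_error(
    assemble_metric_vector(list(a = c(lf_freq_react = 1), b = c(lf_freq_react = 2))),
    "duplicate"
  )
  expect_error(assemble_metric_vector(list(a = c(not_a_metric = 1))), "unknown")
})

test_that("frequency metrics stay within [0, 1] on simulated cohorts", {
  reg <- metric_registry()
  freq_ids <- reg$id[reg$units == "fraction" & !grepl("habituation|ppi", reg$id)]
  for (seed in c(5, 6)) {
    m <- compute_metric_matrix(tiny_cohort(n = 10, seed = seed))
    for (id in freq_ids) {
      v <- m[[id]][!is.na(m[[id]])]
      expect_true(all(v >= 0 & v <= 1))
    }
    # habituation and PPI never exceed 1
    for (id in c("df_habituation", "asr_habituation", "asr_ppi")) {
      v <- m[[id]][!is.na(m[[id]])]
      expect_true(all(v <= 1))
    }
  }
})

test_that("frequency estimators tighten as stimulus counts scale up", {
  # LF with 10x the stimuli: the react-frequency estimator concentrates
  p <- build_default_protocol()
  lf_big <- assay_block("LF", 500, 500, local({
    ev <- events_of(p, "LF")
    n <- 150
    data.frame(
      onset_ms = seq(0, by = 30000, length.out = n),
      kind = "light_flash", intensity = "none",
      prepulse_intensity = NA_character_, prepulse_lead_ms = NA_real_,
      duration_ms = 500, recorded = TRUE, block_id = "LF",
      stimulus_index = seq_len(n), stringsAsFactors = FALSE
    )
  }))
  proto_big <- protocol(list(p$blocks$VMR, lf_big, p$blocks$DF, p$blocks$ASR))
  cfg <- cohort_config(n_larvae = 40, genotype_proportions = c(wt = 1), seed = 55)
  m_small <- compute_metric_matrix(simulate_cohort(cfg, p, assays = "LF"))
  m_big <- compute_metric_matrix(simulate_cohort(cfg, proto_big, assays = "LF"))
  truth <- 0.6 * pnorm(0.5, 1.1, 0.3, lower.tail = FALSE)
  expect_lt(
    sd(m_big$lf_freq_react),
    sd(m_small$lf_freq_react)
  )
  expect_lt(abs(mean(m_big$lf_freq_react) - truth), 0.03)
})
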