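test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  cfg <- cohort_config(n_larvae = 4, seed = 99)
  a <- simulate_cohort(cfg, mode = "kinematic")
  b <- simulate_cohort(cfg, mode = "kinematic")
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$events, b$events)
  expect_identical(a$vmr_bouts, b$vmr_bouts)
  expect_identical(a$trajectories, b$trajectories)
})

test_that("degenerate probabilities force deterministic responses", {
  p1 <- behavior_params(
    p_respond = c(light_flash = 1, dark_flash = 1),
    sensitivity_curve = c(low = 1, medium = 1, high = 1),
    habituation_rate = 0,
    ppi_strength = 0,
    slc_fraction = 1,
    curvature_params = list(
      slc = c(mean = 2.2, sd = 0.01, min = 0.2),
      llc = c(mean = 2.2, sd = 0.01, min = 0.2),
      obend = c(mean = 2.6, sd = 0.01, min = 0.2), # forces peaks > 1.75 rad
      react = c(mean = 1.1, sd = 0.01, min = 0.2)
    )
  )
  cfg <- cohort_config(
    n_larvae = 6, genotype_proportions = c(wt = 1),
    params = list(wt = p1), seed = 3
  )
  co <- simulate_cohort(cfg, assays = c("DF", "ASR"))
  df_ev <- co$events[co$events$assay == "DF", ]
  expect_true(all(df_ev$responded))
  expect_true(all(df_ev$label == "obend"))
  m <- compute_metric_matrix(co)
  expect_equal(m$df_freq_obend, rep(1, 6))
  expect_equal(m$df_habituation, rep(0, 6)) # no decay
  expect_equal(m$asr_ppi, rep(0, 6)) # no prepulse suppression

  p0 <- behavior_params(
    p_respond = c(light_flash = 0, dark_flash = 0),
    sensitivity_curve = c(low = 0, medium = 0, high = 0)
  )
  cfg0 <- cohort_config(
    n_larvae = 3, genotype_proportions = c(wt = 1),
    params = list(wt = p0), seed = 4
  )
  co0 <- simulate_cohort(cfg0, assays = c("LF", "DF", "ASR"))
  expect_true(all(!co0$events$responded))
  m0 <- compute_metric_matrix(co0)
  expect_equal(m0$lf_freq_no_movement, rep(1, 3))
  expect_true(all(is.na(m0$lf_avg_latency_ms)))
  expect_true(all(is.na(m0$asr_habituation))) # baseline SLC frequency zero
})

test_that("per-stimulus response frequency follows geometric habituation", {
  p <- behavior_params(habituation_rate = 0.5)
  cfg <- cohort_config(
    n_larvae = 500, genotype_proportions = c(wt = 1),
    params = list(wt = p), seed = 17
  )
  co <- simulate_cohort(cfg, assays = "DF")
  ev <- co$events
  freq <- tapply(ev$responded, ev$train_index, mean)
  expected <- 0.8 * (1 - 0.5)^(0:13)
  se <- sqrt(expected * (1 - expected) / (500 * 3)) # 3 recorded blocks
  expect_true(all(abs(freq - expected) < pmax(4 * se, 0.01)))
})

test_that("genotype proportions converge to the configured incross ratios", {
  rejections <- 0
  for (s in 1:20) {
    cfg <- cohort_config(n_larvae = 2000, seed = s)
    co <- simulate_cohort(cfg, assays = character(0))
    counts <- table(factor(co$genotypes$genotype, levels = c("wt", "het", "mut")))
    pval <- suppressWarnings(
      chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
    )
    if (pval < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})

test_that("latent SLC/LLC latencies separate cleanly at 20 ms", {
  cfg <- cohort_config(n_larvae = 40, seed = 23)
  co <- simulate_cohort(cfg, assays = "ASR")
  resp <- co$events[co$events$responded, ]
  expect_true(all(resp$latency_ms[resp$latent_class == "slc"] < 20))
  expect_true(all(resp$latency_ms[resp$latent_class == "llc"] > 20))
  acc <- mean(resp$label == resp$latent_class)
  expect_gt(acc, 0.99)
})

test_that("simulated positions stay inside the 9 mm well", {
  co <- tiny_cohort(n = 10, seed = 31, assays = "VMR")
  r <- sqrt(co$vmr_positions$x^2 + co$vmr_positions$y^2)
  expect_true(all(r <= co$well_radius_px + 1e-9))
  expect_equal(co$well_radius_px, 45) # 4.5 mm radius at 10 px/mm
})

test_that("parameter recovery is centered on the generating values", {
  # PPI estimator converges to ppi_strength at large n
  p <- behavior_params(ppi_strength = 0.6, habituation_rate = 0)
  cfg <- cohort_config(
    n_larvae = 300, genotype_proportions = c(wt = 1),
    params = list(wt = p), seed = 41
  )
  co <- simulate_cohort(cfg, assays = c("ASR", "DF", "LF"))
  m <- compute_metric_matrix(co)
  rec <- recover_parameters(m, co)
  ppi <- rec[rec$parameter == "ppi", ]
  expect_equal(ppi$expected, 0.6)
  expect_lt(abs(ppi$bias), 0.05)
  # no decay: habituation metric centered on 0
  hab <- rec[rec$parameter == "habituation_asr", ]
  expect_equal(hab$expected, 0)
  expect_lt(abs(hab$bias), 0.05)
  hab_direct <- mean(m$asr_habituation, na.rm = TRUE)
  expect_lt(abs(hab_direct), 0.06)

  # Poisson bout counts match the thinned closed-form expectation
  co_v <- tiny_cohort(n = 60, seed = 43, assays = "VMR")
  m_v <- compute_metric_matrix(co_v)
  rec_v <- recover_parameters(m_v, co_v)
  for (par in c("bouts_light", "bouts_dark")) {
    row <- rec_v[rec_v$parameter == par & rec_v$genotype == "het", ]
    expect_lt(abs(row$bias) / row$expected, 0.1)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(behavior_params(ppi_strength = 1.4), "probabilities")
  expect_error(behavior_params(bout_rate_per_min = c(light = -1, dark = 2)), "rates")
  expect_error(
    behavior_params(latency_params = list(
      slc = c(mean = 25, sd = 1, min = 4, max = 40),
      llc = c(mean = 45, sd = 10, min = 24, max = 120),
      obend = c(mean = 120, sd = 40, min = 25, max = 600),
      react = c(mean = 60, sd = 20, min = 20, max = 300)
    )),
    "latency mean"
  )
  expect_error(cohort_config(genotype_proportions = c(wt = 0.5, mut = 0.4)), "sum to 1")
  expect_error(cohort_config(n_larvae = 0), "n_larvae")
  expect_error(cohort_config(seed = NA), "seed")
})
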