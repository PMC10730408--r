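test_that("pooled t test matches the textbook computation and stats::t.test", {
  r <- metric_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  a <- c(0, 0, 1, 1)
  b <- c(1, 1, 2, 2)
  got <- metric_ttest(a, b)
  want <- oracle_pooled_t(a, b)
  expect_equal(got$t, want$t)
  expect_equal(got$p, want$p)

  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    got <- metric_ttest(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }

  expect_error(metric_ttest(5, c(1, 2, 3)), "at least two")
  # degenerate: zero pooled variance
  same <- metric_ttest(c(2, 2, 2), c(2, 2))
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  apart <- metric_ttest(c(2, 2, 2), c(3, 3))
  expect_equal(apart$p, 0)
  expect_true(apart$degenerate)
  # missing values are dropped
  expect_equal(metric_ttest(c(a, NA), b)$t, want$t)
})

test_that("reproducibility filter requires p < alpha in both experiments", {
  p1 <- c(m1 = 0.01, m2 = 0.01, m3 = 0.2, m4 = NA)
  p2 <- c(m1 = 0.2, m2 = 0.01, m3 = 0.01, m4 = 0.01)
  expect_equal(reproducibility_filter(p1, p2), "m2")
  expect_equal(length(reproducibility_filter(
    c(m1 = 0.01, m2 = 0.5), c(m1 = 0.5, m2 = 0.01)
  )), 0) # disjoint significant sets -> line drops from pooling
  expect_error(reproducibility_filter(c(a = 0.1), c(b = 0.1)), "registries")
})

test_that("sibling normalization yields unit sibling means per experiment", {
  mk <- function(sib_vals, mut_vals) {
    data.frame(
      larva_id = sprintf("L%d", seq_len(length(sib_vals) + length(mut_vals))),
      genotype = c(rep("wt", length(sib_vals)), rep("mut", length(mut_vals))),
      treatment = "E3",
      lf_freq_react = c(sib_vals, mut_vals),
      stringsAsFactors = FALSE
    )
  }
  e1 <- mk(c(2, 2, 2), 3)
  pooled <- normalize_and_pool(list(e1))
  expect_equal(pooled$lf_freq_react, c(1, 1, 1, 1.5))

  e2 <- mk(c(4, 4, 4), 2)
  pooled2 <- normalize_and_pool(list(e1, e2))
  for (ex in 1:2) {
    sib <- pooled2$genotype != "mut" & pooled2$experiment == ex
    expect_equal(mean(pooled2$lf_freq_react[sib]), 1)
  }

  # idempotence on already-normalized data
  renorm <- normalize_and_pool(list(pooled[, names(e1)]))
  expect_equal(renorm$lf_freq_react, pooled$lf_freq_react)

  # sibling mean zero: metric excluded with a warning
  e0 <- mk(c(0, 0, 0), 1)
  expect_warning(out <- normalize_and_pool(list(e0)), "sibling mean zero")
  expect_true(all(is.na(out$lf_freq_react)))
  expect_equal(attr(out, "excluded_metrics"), "lf_freq_react")
})

test_that("Bonferroni screening uses the 0.05/94 threshold", {
  expect_true(0.0004 < 0.05 / 94)
  expect_false(0.01 < 0.05 / 94) # 0.01 never survives alpha/94 for alpha <= 0.94
  set.seed(8)
  n <- 40
  m <- data.frame(
    larva_id = sprintf("L%03d", 1:(2 * n)),
    genotype = rep(c("wt", "mut"), each = n),
    treatment = "E3",
    lf_freq_react = c(rnorm(n, 10, 1), rnorm(n, 12, 1)), # strong effect
    df_freq_obend = rnorm(2 * n, 5, 1), # null
    stringsAsFactors = FALSE
  )
  scr <- bonferroni_screen(normalize_and_pool(list(m)))
  strong <- scr[scr$metric == "lf_freq_react", ]
  expect_true(strong$significant)
  expect_lt(strong$pooled_p, 0.05 / 94)
  null_m <- scr[scr$metric == "df_freq_obend", ]
  expect_false(null_m$significant)
})

test_that("SD differences are sibling-SD units with the published sign", {
  m <- data.frame(
    larva_id = sprintf("L%02d", 1:8),
    genotype = c(rep("wt", 5), rep("mut", 3)),
    treatment = "E3",
    lf_avg_latency_ms = c(8, 9, 10, 11, 12, 6, 6, 6),
    stringsAsFactors = FALSE
  )
  scr <- bonferroni_screen(m) # un-normalized input: direct arithmetic
  row <- scr[scr$metric == "lf_avg_latency_ms", ]
  sib_sd <- sd(c(8, 9, 10, 11, 12))
  expect_equal(row$sd_difference, (6 - 10) / sib_sd) # negative = lower in mutant
  # mutant mean equal to sibling mean: 0 SD, unmasked
  m$lf_avg_latency_ms <- c(8, 10, 12, 10, 10, 8, 10, 12)
  scr2 <- bonferroni_screen(m)
  expect_equal(scr2$sd_difference[1], 0)
  expect_false(scr2$significant[1])
  # zero sibling SD: cell missing
  m$lf_avg_latency_ms <- c(7, 7, 7, 7, 7, 8, 10, 12)
  expect_true(is.na(bonferroni_screen(m)$sd_difference[1]))
})

test_that("heatmap assembles lines by metrics with a significance mask", {
  co1 <- tiny_cohort(n = 30, seed = 61)
  co2 <- tiny_cohort(n = 30, seed = 62)
  m1 <- compute_metric_matrix(co1)
  m2 <- compute_metric_matrix(co2)
  scr <- run_screen(list(m1, m2))
  hm <- heatmap_matrix(list(lineA = scr, lineB = scr))
  expect_equal(dim(hm$sd), c(2, 94))
  expect_equal(dim(hm$mask), c(2, 94))
  expect_equal(colnames(hm$sd), scr$metric)
})

test_that("one-way ANOVA matches t-squared for two groups and finds planted trends", {
  x <- c(1.2, 3.1, 2.2, 0.5, 2.8, 3.3, 4.0, 2.9)
  g <- rep(c("a", "b"), each = 4)
  a <- multi_group_anova(x, g)
  t2 <- metric_ttest(x[g == "a"], x[g == "b"])
  expect_equal(a$F, t2$t^2, tolerance = 1e-10)
  expect_equal(a$p, t2$p, tolerance = 1e-10)

  # identical groups: F = 0, p = 1
  ident <- multi_group_anova(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(ident$F, 0)
  expect_equal(ident$p, 1)

  # planted ordered means across three genotype groups
  set.seed(19)
  v <- c(rnorm(40, 0), rnorm(40, 0.5), rnorm(40, 1))
  g3 <- rep(c("wt", "het", "mut"), each = 40)
  res <- multi_group_anova(v, g3)
  expect_lt(res$p, 0.001)
  expect_s3_class(as.data.frame(res$pairwise), "data.frame")

  expect_error(multi_group_anova(1:4, rep("a", 4)), "two groups")
  expect_error(multi_group_anova(1:4, c("a", "a", "a", "b")), "at least two values")
})

test_that("the single-experiment exception path is recorded", {
  co <- tiny_cohort(n = 30, seed = 63)
  m <- compute_metric_matrix(co)
  scr <- run_screen(list(m), single_experiment = TRUE)
  expect_true(attr(scr, "single_experiment"))
  expect_true(all(is.na(scr$p_exp2)))
  expect_error(run_screen(list(m), single_experiment = FALSE), "two experiments")
})
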