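# Mutant-versus-sibling screening statistics: per-metric t tests,
# two-experiment reproducibility, sibling normalization, pooled
# Bonferroni-corrected testing, SD-difference heatmaps, one-way ANOVA.

#' Pooled-variance two-sample t test
#'
#' Two-tailed, unpaired Student's t with pooled variance. Missing values
#' are dropped per group. If both groups are identical constants the test
#' is degenerate with `t = 0, p = 1`; zero pooled variance with unequal
#' means yields the 0-limit p with a degenerate flag.
#'
#' @param a,b Numeric vectors (each needs at least two non-missing values).
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
metric_ttest <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least two non-missing values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  delta <- mean(a) - mean(b)
  if (se == 0) {
    if (delta == 0) {
      return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(delta) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  t <- delta / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

split_contrast <- function(metrics, mutant = "mut", sibling = c("wt", "het")) {
  list(
    mut = metrics[metrics$genotype %in% mutant, , drop = FALSE],
    sib = metrics[metrics$genotype %in% sibling, , drop = FALSE]
  )
}

metric_columns <- function(metrics, registry = metric_registry()) {
  intersect(registry$id, names(metrics))
}

# Per-metric mutant-vs-sibling p values for one experiment's metric matrix.
experiment_pvalues <- function(metrics, mutant = "mut", sibling = c("wt", "het"),
                               registry = metric_registry()) {
  g <- split_contrast(metrics, mutant, sibling)
  cols <- metric_columns(metrics, registry)
  p <- vapply(cols, function(cn) {
    a <- g$mut[[cn]]
    b <- g$sib[[cn]]
    if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) {
      return(NA_real_)
    }
    metric_ttest(a, b)$p
  }, numeric(1))
  stats::setNames(p, cols)
}

#' Metrics reproducible across two experiments
#'
#' @param p_exp1,p_exp2 Named per-metric p-value vectors from two
#'   independent experiments on the same line.
#' @param alpha Per-experiment significance level.
#' @return Character vector of metric ids with `p < alpha` in both
#'   experiments (possibly empty, in which case the line drops out of
#'   pooling).
#' @export
reproducibility_filter <- function(p_exp1, p_exp2, alpha = 0.05) {
  if (!identical(names(p_exp1), names(p_exp2))) {
    stop("experiments carry different metric registries")
  }
  names(p_exp1)[!is.na(p_exp1) & !is.na(p_exp2) & p_exp1 < alpha & p_exp2 < alpha]
}

#' Normalize metrics by the sibling mean and pool experiments
#'
#' Within each experiment every metric value is divided by that
#' experiment's mean sibling value, so the normalized sibling mean is
#' exactly 1 per experiment; experiments are then concatenated. Metrics
#' whose sibling mean is (numerically) zero in any experiment cannot be
#' normalized and are excluded with a warning.
#'
#' @param experiments List of metric matrices (as from
#'   [compute_metric_matrix()]), one per experiment.
#' @param mutant,sibling Genotype labels forming the contrast.
#' @param registry The [metric_registry()].
#' @return The pooled metric matrix with an `experiment` column; excluded
#'   metric ids in attribute `excluded_metrics`.
#' @export
normalize_and_pool <- function(experiments, mutant = "mut",
                               sibling = c("wt", "het"),
                               registry = metric_registry()) {
  cols <- metric_columns(experiments[[1]], registry)
  excluded <- character(0)
  normed <- lapply(seq_along(experiments), function(i) {
    m <- experiments[[i]]
    sib <- m[m$genotype %in% sibling, , drop = FALSE]
    for (cn in cols) {
      mu <- mean(sib[[cn]], na.rm = TRUE)
      if (!is.finite(mu) || abs(mu) < 1e-12) {
        excluded <<- union(excluded, cn)
        m[[cn]] <- NA_real_
      } else {
        m[[cn]] <- m[[cn]] / mu
      }
    }
    m$experiment <- i
    m
  })
  if (length(excluded)) {
    warning(
      "metrics excluded from pooling (sibling mean zero): ",
      paste(excluded, collapse = ", ")
    )
  }
  pooled <- do.call(rbind, normed)
  attr(pooled, "excluded_metrics") <- excluded
  pooled
}

#' Bonferroni-corrected pooled screen
#'
#' Per-metric pooled-variance t tests on normalized pooled data; a metric
#' is significant when its pooled p value is below `alpha / m` with `m`
#' fixed at the registry size (94) regardless of missing metrics, matching
#' the published correction. The SD difference is the pooled normalized
#' mutant mean minus sibling mean in units of the pooled sibling SD.
#'
#' @param pooled Output of [normalize_and_pool()].
#' @param alpha Family-wise error target.
#' @param m Number of comparisons for the Bonferroni divisor.
#' @param mutant,sibling Genotype labels forming the contrast.
#' @param registry The [metric_registry()].
#' @return Data frame (one row per metric): `metric`, `pooled_p`,
#'   `significant`, `mut_mean`, `sib_mean`, `sd_difference`.
#' @export
bonferroni_screen <- function(pooled, alpha = 0.05, m = 94,
                              mutant = "mut", sibling = c("wt", "het"),
                              registry = metric_registry()) {
  cols <- metric_columns(pooled, registry)
  g <- split_contrast(pooled, mutant, sibling)
  rows <- lapply(cols, function(cn) {
    a <- g$mut[[cn]]
    b <- g$sib[[cn]]
    ok <- sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2
    p <- if (ok) metric_ttest(a, b)$p else NA_real_
    sib_sd <- stats::sd(b, na.rm = TRUE)
    data.frame(
      metric = cn,
      pooled_p = p,
      significant = !is.na(p) & p < alpha / m,
      mut_mean = mean(a, na.rm = TRUE),
      sib_mean = mean(b, na.rm = TRUE),
      sd_difference = if (isTRUE(sib_sd > 0)) {
        (mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)) / sib_sd
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  out
}

#' Run the full two-experiment screen for one line
#'
#' Reproduces the published procedure: per-experiment two-tailed Student's
#' t tests mutant versus sibling on all 94 metrics; metrics with p < 0.05
#' in both experiments are reproducible; data are normalized by the
#' per-experiment sibling mean, pooled, and re-tested under Bonferroni
#' alpha/94. A metric is "called" when it is reproducible and survives the
#' pooled correction. Lines assayed once can skip the reproducibility
#' filter (`single_experiment = TRUE`), which is recorded in the result.
#'
#' @param experiments List of one or two metric matrices.
#' @param mutant,sibling Genotype labels forming the contrast (sibling
#'   defaults to all non-homozygous-mutant larvae; use `sibling = "wt"`
#'   for lines where heterozygotes are compared to wildtypes).
#' @param alpha Significance level.
#' @param m Bonferroni divisor (94).
#' @param single_experiment Skip the reproducibility filter.
#' @param registry The [metric_registry()].
#' @return A `screen_result` data frame: per metric `p_exp1`, `p_exp2`,
#'   `reproducible`, `pooled_p`, `significant`, `called`, `mut_mean`,
#'   `sib_mean`, `sd_difference`; provenance in attributes.
#' @export
run_screen <- function(experiments, mutant = "mut", sibling = c("wt", "het"),
                       alpha = 0.05, m = 94, single_experiment = length(experiments) == 1,
                       registry = metric_registry()) {
  if (!single_experiment && length(experiments) < 2) {
    stop("two experiments are required unless single_experiment = TRUE")
  }
  p1 <- experiment_pvalues(experiments[[1]], mutant, sibling, registry)
  if (single_experiment) {
    repro_ids <- names(p1)[!is.na(p1) & p1 < alpha]
    p2 <- stats::setNames(rep(NA_real_, length(p1)), names(p1))
  } else {
    p2 <- experiment_pvalues(experiments[[2]], mutant, sibling, registry)
    repro_ids <- reproducibility_filter(p1, p2, alpha)
  }
  pooled <- suppressWarnings(normalize_and_pool(experiments, mutant, sibling, registry))
  scr <- bonferroni_screen(pooled, alpha, m, mutant, sibling, registry)
  scr$p_exp1 <- unname(p1[scr$metric])
  scr$p_exp2 <- unname(p2[scr$metric])
  scr$reproducible <- scr$metric %in% repro_ids
  scr$called <- scr$reproducible & scr$significant
  scr <- scr[, c(
    "metric", "p_exp1", "p_exp2", "reproducible", "pooled_p",
    "significant", "called", "mut_mean", "sib_mean", "sd_difference"
  )]
  attr(scr, "alpha") <- alpha
  attr(scr, "m") <- m
  attr(scr, "single_experiment") <- single_experiment
  attr(scr, "contrast") <- list(mutant = mutant, sibling = sibling)
  attr(scr, "excluded_metrics") <- attr(pooled, "excluded_metrics")
  class(scr) <- c("screen_result", class(scr))
  scr
}

#' Assemble the line-by-metric SD-difference heatmap matrix
#'
#' @param results Named list of `screen_result`s, one per mutant line.
#' @return List with `sd` (lines x metrics matrix of signed SD
#'   differences; negative = lower in mutant) and `mask` (logical matrix of
#'   metrics called significant, the cells marked "#" on the published
#'   heatmaps).
#' @export
heatmap_matrix <- function(results) {
  if (!length(results)) stop("at least one screened line is required")
  metrics <- results[[1]]$metric
  sd_mat <- do.call(rbind, lapply(results, function(r) {
    stats::setNames(r$sd_difference, r$metric)[metrics]
  }))
  mask <- do.call(rbind, lapply(results, function(r) {
    stats::setNames(r$called, r$metric)[metrics]
  }))
  rownames(sd_mat) <- rownames(mask) <- names(results)
  list(sd = sd_mat, mask = mask)
}

#' Plot the screen heatmap
#'
#' Blue cells are lower in the mutant than in siblings, red higher;
#' Bonferroni-surviving reproducible metrics are marked "#".
#'
#' @param hm Output of [heatmap_matrix()].
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_screen_heatmap <- function(hm, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("the pheatmap package is required for plotting")
  }
  labels <- ifelse(is.na(hm$sd), "", ifelse(hm$mask, "#", ""))
  lim <- max(abs(hm$sd), na.rm = TRUE)
  ph <- pheatmap::pheatmap(
    hm$sd,
    cluster_rows = FALSE, cluster_cols = FALSE,
    display_numbers = labels,
    breaks = seq(-lim, lim, length.out = 101),
    color = grDevices::colorRampPalette(c("blue", "white", "red"))(100),
    ...
  )
  invisible(ph)
}

#' One-way ANOVA across genotype or treatment groups
#'
#' Used for single-figure contrasts and multi-genotype (e.g. double-mutant)
#' comparisons. With two groups the F statistic equals the square of the
#' pooled t statistic. Degenerate inputs with zero between- and
#' within-group variance return `F = 0, p = 1`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (same length).
#' @return List with `F`, `df`, `p` and `pairwise` (Tukey HSD table, or
#'   `NULL` when degenerate).
#' @export
multi_group_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2) stop("at least two groups are required")
  if (any(table(groups) < 2)) stop("each group needs at least two values")
  if (stats::var(values) == 0) {
    return(list(
      F = 0, df = c(nlevels(groups) - 1, length(values) - nlevels(groups)),
      p = 1, pairwise = NULL
    ))
  }
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  list(
    F = s[["F value"]][1],
    df = c(s[["Df"]][1], s[["Df"]][2]),
    p = s[["Pr(>F)"]][1],
    pairwise = stats::TukeyHSD(fit)$groups
  )
}
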