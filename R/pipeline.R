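# Orchestration and format round-tripping. The package's entry points are
# its exported functions; run_pipeline() chains simulate/track ->
# kinematics -> metrics -> screen and writes every interface file plus a
# manifest that fully determines reproduction.
#
# CSV dialect: UTF-8, comma separated, '.' decimal, mandatory header,
# missing values as empty fields. Screen results are tab separated.

TRAJECTORY_COLUMNS <- c(
  "larva_id", "assay", "block_id", "stimulus_index", "frame", "time_ms",
  "x", "y", "curvature_rad", "orientation_rad"
)

#' Write / read trajectory CSV
#'
#' @param traj Trajectory data frame (one or more larvae).
#' @param path File path.
#' @return `path` (write) or the trajectory data frame (read).
#' @export
write_trajectory_csv <- function(traj, path) {
  missing_cols <- setdiff(TRAJECTORY_COLUMNS, names(traj))
  if (length(missing_cols)) {
    stop("trajectory missing columns: ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(traj[, union(TRAJECTORY_COLUMNS, names(traj))],
    path,
    row.names = FALSE, na = ""
  )
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(TRAJECTORY_COLUMNS, names(tr))
  if (length(missing_cols)) {
    stop("malformed trajectory file ", path, ": missing columns ",
      paste(missing_cols, collapse = ", "))
  }
  num <- c("frame", "time_ms", "x", "y", "curvature_rad", "orientation_rad")
  for (cn in num) {
    v <- tr[[cn]]
    bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
    if (length(bad)) {
      stop(
        "malformed trajectory file ", path, ": non-numeric '", cn,
        "' at data row ", bad[1]
      )
    }
    tr[[cn]] <- as.numeric(v)
  }
  tr$stimulus_index <- as.integer(tr$stimulus_index)
  tr
}

#' Write / read the metric matrix CSV
#'
#' Rows are larvae; columns are `larva_id`, `genotype`, `treatment` and the
#' 94 metric ids.
#'
#' @param metrics Metric matrix from [compute_metric_matrix()].
#' @param path File path.
#' @return `path` (write) or the metric matrix (read).
#' @export
write_metric_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metric_csv
#' @export
read_metric_csv <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  ids <- intersect(metric_registry()$id, names(m))
  if (!length(ids)) stop("malformed metric file ", path, ": no registry metric columns")
  for (cn in ids) m[[cn]] <- as.numeric(m[[cn]])
  m
}

#' Write / read screen results TSV
#'
#' @param screen A `screen_result` from [run_screen()].
#' @param path File path.
#' @return `path` (write) or the screen table (read).
#' @export
write_screen_tsv <- function(screen, path) {
  utils::write.table(screen, path,
    sep = "\t", row.names = FALSE, quote = FALSE, na = ""
  )
  invisible(path)
}

#' @rdname write_screen_tsv
#' @export
read_screen_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Export a simulated cohort's genotype table
#'
#' @param cohort A `larva_cohort`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(cohort, path) {
  utils::write.csv(cohort$genotypes, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> kinematics -> metrics -> screen and
#' writes every interface file plus a JSON manifest (seed, mode, contrast,
#' alpha, Bonferroni divisor, package version) that reproduces the run
#' bit-for-bit. With `input = "simulate"` two experiments are simulated
#' with derived seeds and screened; with `input = "trajectories"` a
#' trajectory CSV is loaded and carried through metrics.
#'
#' @param input `"simulate"` or `"trajectories"`.
#' @param out_dir Output directory (created if needed).
#' @param config A [cohort_config()] (simulate mode).
#' @param protocol A `protocol`.
#' @param trajectory_path Trajectory CSV (trajectories mode).
#' @param genotype_path Optional genotype CSV (trajectories mode) with
#'   columns `larva_id`, `genotype`, `treatment`.
#' @param mode Simulation mode passed to [simulate_cohort()].
#' @param mutant,sibling Contrast labels for the screen.
#' @param alpha,m Screen significance level and Bonferroni divisor.
#' @param seed Run seed (overrides the config seed).
#' @param thresholds A [kinematic_thresholds()] object.
#' @return Invisibly, a list with `metrics` (per experiment), `screen`,
#'   `manifest` and the written file paths.
#' @export
run_pipeline <- function(input = c("simulate", "trajectories"),
                         out_dir,
                         config = cohort_config(),
                         protocol = build_default_protocol(),
                         trajectory_path = NULL,
                         genotype_path = NULL,
                         mode = "events",
                         mutant = "mut", sibling = c("wt", "het"),
                         alpha = 0.05, m = 94,
                         seed = config$seed,
                         thresholds = kinematic_thresholds()) {
  input <- match.arg(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    protocol = file.path(out_dir, "protocol.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_protocol(protocol, paths$protocol)
  manifest <- list(
    package = "larvascreen",
    version = as.character(utils::packageVersion("larvascreen")),
    input = input, mode = mode, seed = seed,
    contrast = list(mutant = mutant, sibling = sibling),
    alpha = alpha, m = m
  )

  result <- list(paths = paths)
  if (input == "simulate") {
    metrics <- list()
    screen_input <- list()
    for (e in 1:2) {
      cfg <- config
      cfg$seed <- as.integer(seed + (e - 1L))
      cohort <- simulate_cohort(cfg, protocol, mode = mode)
      mm <- compute_metric_matrix(cohort, thresholds)
      paths[[paste0("metrics_exp", e)]] <- file.path(out_dir, sprintf("metrics_exp%d.csv", e))
      paths[[paste0("genotypes_exp", e)]] <- file.path(out_dir, sprintf("genotypes_exp%d.csv", e))
      write_metric_csv(mm, paths[[paste0("metrics_exp", e)]])
      write_genotype_csv(cohort, paths[[paste0("genotypes_exp", e)]])
      metrics[[e]] <- mm
      screen_input[[e]] <- mm
    }
    scr <- run_screen(screen_input, mutant, sibling, alpha, m)
    paths$screen <- file.path(out_dir, "screen.tsv")
    write_screen_tsv(scr, paths$screen)
    manifest$experiment_seeds <- c(seed, seed + 1L)
    manifest$n_larvae <- config$n_larvae
    result$metrics <- metrics
    result$screen <- scr
  } else {
    if (is.null(trajectory_path)) stop("trajectories mode requires trajectory_path")
    traj <- read_trajectory_csv(trajectory_path)
    genotypes <- if (!is.null(genotype_path)) {
      utils::read.csv(genotype_path, stringsAsFactors = FALSE)
    } else {
      data.frame(
        larva_id = unique(traj$larva_id),
        genotype = NA_character_, treatment = NA_character_,
        stringsAsFactors = FALSE
      )
    }
    cohort <- list(
      genotypes = genotypes,
      trajectories = split(traj, traj$larva_id),
      events = NULL, vmr_bouts = NULL, vmr_positions = NULL,
      protocol = protocol,
      assays = intersect(names(protocol$blocks), unique(traj$assay)),
      mode = "kinematic",
      well_radius_px = 45
    )
    mm <- compute_metric_matrix(cohort, thresholds)
    paths$metrics <- file.path(out_dir, "metrics.csv")
    write_metric_csv(mm, paths$metrics)
    result$metrics <- list(mm)
  }

  result$manifest <- manifest
  result$paths <- paths
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(result)
}
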