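#' Pipeline configuration
#'
#' Bundles the stage configurations for an end-to-end run: cohort generation,
#' risk labelling, per-speed model training, and evaluation. A single global
#' seed fans out deterministically to per-stage seeds so each stage is
#' independently reproducible.
#'
#' @param seed global integer seed.
#' @param out_dir output directory for artifacts.
#' @param n_participants cohort size (default: the published 746).
#' @param speeds walking-speed models to fit.
#' @param model named list of [model_config()] overrides.
#' @param cohort named list of [cohort_spec()] overrides (e.g. `p_high_risk`).
#' @param cv_grid optional data frame of hyperparameter candidates for
#'   cross-validated selection; `NULL` skips tuning and uses the defaults.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("gaitfall_run_"),
                            n_participants = 746L,
                            speeds = GAIT_SPEEDS, model = list(),
                            cohort = list(), cv_grid = NULL) {
  if (!is_count(abs(seed))) gf_param_error("seed must be an integer")
  speeds <- match.arg(speeds, GAIT_SPEEDS, several.ok = TRUE)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_participants = as.integer(n_participants), speeds = speeds,
                 model = model, cohort = cohort, cv_grid = cv_grid),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose keys mirror the [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config_json <- function(path) {
  if (!file.exists(path)) gf_param_error("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "out_dir", "n_participants", "speeds", "model", "cohort", "cv_grid")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) gf_param_error("unknown config keys: %s", paste(unknown, collapse = ", "))
  if (!is.null(raw$cv_grid)) raw$cv_grid <- as.data.frame(raw$cv_grid)
  do.call(pipeline_config, raw)
}

# Derive independent per-stage seeds from the global seed.
fan_out_seeds <- function(seed, n = 4L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the full synthetic-cohort fall-risk pipeline
#'
#' Simulates a labelled cohort, verifies the labels against the questionnaire
#' rule, makes a stratified 70/30 split, optionally tunes hyperparameters by
#' cross-validation on the training set, trains one boosted-tree model per
#' walking speed, and evaluates each on the holdout. Artifacts (cohort CSV,
#' model and report JSON per speed, and a manifest with seeds and file
#' hashes) are written to the configured output directory.
#'
#' @param config a [pipeline_config()] or the path to a JSON config.
#' @return invisible list with the cohort, per-speed models and reports, and
#'   the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config_json(config)
  if (!inherits(config, "pipeline_config")) {
    gf_param_error("config must be a pipeline_config or a JSON path")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- fan_out_seeds(config$seed, 3L)

  cohort_args <- config$cohort
  cohort_args$seed <- seeds[1]
  cohort_args$n_participants <- config$n_participants
  spec <- do.call(default_cohort_spec, cohort_args)
  cohort <- simulate_cohort(spec)
  relabel <- label_cohort(cohort, spec$rule)
  if (!identical(relabel, cohort$risk_label)) {
    gf_data_error("generated labels do not round-trip through the risk rule")
  }
  cohort_path <- file.path(config$out_dir, "cohort.csv")
  write_cohort_csv(cohort, cohort_path)

  model_args <- config$model
  model_args$seed <- seeds[2]
  cfg <- do.call(model_config, model_args)
  parts <- split_train_test(cohort, cfg$train_fraction, seed = cfg$seed)

  models <- list(); reports <- list(); files <- cohort_path
  for (speed in config$speeds) {
    feats <- speed_feature_set(speed)
    speed_cfg <- cfg
    if (!is.null(config$cv_grid)) {
      speed_cfg <- cross_validate(parts$train, cfg, feats, grid = config$cv_grid)$config
    }
    model <- train_model(parts$train, speed_cfg, feats)
    report <- full_report(model, parts$test, speed)
    mp <- file.path(config$out_dir, sprintf("model_%s.json", speed))
    rp <- file.path(config$out_dir, sprintf("report_%s.json", speed))
    save_model_json(model, mp)
    write_report_json(report, rp)
    models[[speed]] <- model
    reports[[speed]] <- report
    files <- c(files, mp, rp)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gaitfall")),
    global_seed = config$seed,
    stage_seeds = list(cohort = seeds[1], model = seeds[2], reserved = seeds[3]),
    n_participants = config$n_participants,
    speeds = config$speeds,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, models = models, reports = reports,
                 manifest = manifest, split = parts))
}
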