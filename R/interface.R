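# default run configuration; every key can be overridden by the config file
.kin_default_config <- function() {
  list(motion = "squat", p = 50L, n_trials = 1L, K = 15L,
       noise_sd = 0.02, manifest = NA_character_,
       variance_levels = c(0.80, 0.90, 0.95, 0.98),
       T_g = 200L, T_s = 2000L, B = 199L,
       n_grid = NA, n_pc = NA, trim_frac = 0.05,
       seed = 1L, out_dir = "kineticsm-run")
}

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Comma-separated
#' values become numeric vectors. Unknown keys are an error. Keys:
#' `motion, p, n_trials, K, noise_sd, manifest, variance_levels, T_g, T_s,
#' B, n_grid, n_pc, trim_frac, seed, out_dir`.
#'
#' @param path Path to the config file, or `NULL` for all defaults.
#' @param overrides Named list applied on top of the file (used for CLI
#'   flags).
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- .kin_default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        stop("malformed config line: '", ln, "'")
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg))
        stop("unknown config key: '", key, "'")
      cfg[[key]] <- .kin_coerce_config(key, val)
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) stop("unknown config key: '", key, "'")
    cfg[[key]] <- overrides[[key]]
  }
  .kin_validate_config(cfg)
}

.kin_coerce_config <- function(key, val) {
  if (key %in% c("motion", "manifest", "out_dir")) return(val)
  parts <- strsplit(val, ",", fixed = TRUE)[[1]]
  num <- suppressWarnings(as.numeric(trimws(parts)))
  if (anyNA(num)) stop("config key '", key, "' must be numeric, got '",
                       val, "'")
  num
}

.kin_validate_config <- function(cfg) {
  cfg$motion <- .kin_check_motion(cfg$motion)
  if (any(cfg$variance_levels <= 0) || any(cfg$variance_levels > 1))
    stop("variance_levels must be in (0, 1]")
  if (!is.na(cfg$seed) && cfg$seed != round(cfg$seed))
    stop("seed must be an integer")
  for (key in c("p", "n_trials", "K", "T_g", "T_s", "B", "seed"))
    cfg[[key]] <- as.integer(cfg[[key]])
  if (cfg$p < 4L) stop("config error: p must be >= 4")
  cfg
}

.kin_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

.kin_provenance <- function(cfg, stage, dir) {
  jsonlite::write_json(
    list(stage = stage, config = cfg,
         package_version = as.character(utils::packageVersion("kineticsm")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, paste0(stage, "_provenance.json")),
    digits = NA, auto_unbox = TRUE)
}

#' Simulate and write a synthetic cohort
#'
#' Generates a ground-truth model and cohort from the configuration and
#' writes the trial files, manifest and ground-truth sidecar under
#' `<out_dir>/cohort/`.
#'
#' @param cfg Configuration list from [read_run_config()].
#' @return Path to the written manifest, invisibly.
#' @export
run_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- make_ground_truth(cfg$motion, K = cfg$K, noise_sd = cfg$noise_sd,
                          seed = cfg$seed)
  trials <- simulate_cohort(gt, p = cfg$p, seed = cfg$seed,
                            n_trials = cfg$n_trials)
  cdir <- file.path(cfg$out_dir, "cohort")
  man <- write_cohort(trials, cdir)
  write_ground_truth(gt, file.path(cdir, "ground_truth.json"),
                     scores = attr(trials, "scores"))
  .kin_provenance(cfg, "simulate", cfg$out_dir)
  .kin_log("simulate", "wrote %d trial(s) for %d subjects to %s",
           length(trials), cfg$p, cdir)
  invisible(man)
}

#' Prepare a cohort and fit the kinetic model
#'
#' Reads the cohort (from `cfg$manifest`, or the manifest written by
#' [run_simulate()] under `cfg$out_dir`), runs preprocessing, fits the
#' principal-mode model and writes `model.json`, a scree table
#' (`scree.tsv`) and mode-band curve data for the first three modes
#' (`mode<k>_curves.tsv`).
#'
#' @param cfg Configuration list.
#' @return The fitted `kinetic_pca`, invisibly.
#' @export
run_fit <- function(cfg) {
  man <- if (!is.na(cfg$manifest)) cfg$manifest
         else file.path(cfg$out_dir, "cohort", "manifest.csv")
  if (!file.exists(man))
    stop("fit stage: manifest not found at '", man,
         "' (run the simulate stage or set 'manifest')")
  trials <- read_cohort(man)
  X <- prep_cohort(trials, trim_frac = cfg$trim_frac)
  fit <- kinetic_pca(X)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_kinetic_pca(fit, file.path(cfg$out_dir, "model.json"))
  write.table(summary(fit)$table, file.path(cfg$out_dir, "scree.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  for (k in seq_len(min(3L, length(fit$eigenvalues)))) {
    mc <- mode_curves(fit, k)
    tab <- data.frame(progress = rep(0:100, each = 6L),
                      channel = rep(.kin_channels, .kin_n_instants),
                      mean = as.vector(mc$mean),
                      plus_2sd = as.vector(mc$plus),
                      minus_2sd = as.vector(mc$minus))
    write.table(tab, file.path(cfg$out_dir, sprintf("mode%d_curves.tsv", k)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  saveX <- file.path(cfg$out_dir, "training_matrix.tsv")
  write.table(unclass(X), saveX, sep = "\t", quote = FALSE)
  .kin_provenance(cfg, "fit", cfg$out_dir)
  .kin_log("fit", "fitted %s model: p = %d, rank %d, 95%% variance in %d modes",
           fit$motion, fit$p, length(fit$eigenvalues),
           n_components_for_variance(fit, 0.95))
  invisible(fit)
}

#' Run the validation suite and write the report
#'
#' Loads the cohort used by [run_fit()], reruns preprocessing, and computes
#' accuracy, compactness, generalization, specificity and the permutation
#' component table at the configured scale, writing the report files under
#' `<out_dir>/validation/`.
#'
#' @param cfg Configuration list.
#' @return The `kin_validation` report, invisibly.
#' @export
run_validate <- function(cfg) {
  man <- if (!is.na(cfg$manifest)) cfg$manifest
         else file.path(cfg$out_dir, "cohort", "manifest.csv")
  if (!file.exists(man))
    stop("validate stage: manifest not found at '", man, "'")
  trials <- read_cohort(man)
  X <- prep_cohort(trials, trim_frac = cfg$trim_frac)
  if (nrow(X) != .kin_n_features)
    stop("validate stage: training matrix has ", nrow(X),
         " rows, expected ", .kin_n_features)
  n_values <- if (all(is.na(cfg$n_grid))) NULL else as.integer(cfg$n_grid)
  n_pc <- if (all(is.na(cfg$n_pc))) NULL else as.integer(cfg$n_pc)
  rep <- validate_model(X, variance_levels = cfg$variance_levels,
                        T_g = cfg$T_g, T_s = cfg$T_s, B = cfg$B,
                        n_values = n_values, n_pc = n_pc, seed = cfg$seed)
  vdir <- file.path(cfg$out_dir, "validation")
  write_validation_report(rep, vdir)
  .kin_provenance(cfg, "validate", cfg$out_dir)
  .kin_log("validate", "report written to %s", vdir)
  invisible(rep)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `inst/scripts/kineticsm` Rscript wrapper.
#' Subcommands: `simulate`, `fit`, `validate`, `report` (= all three in
#' sequence). Flags: `--config <path>`, `--seed <int>`, `--motion
#' <squat|lunge>`, `--out <dir>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: kineticsm <simulate|fit|validate|report>",
    "[--config FILE] [--seed INT] [--motion squat|lunge] [--out DIR]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  args <- args[-1]
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--") || i == length(args))
      stop("bad argument '", key, "'\n", usage)
    flags[[substring(key, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  overrides <- list()
  if (!is.null(flags$seed)) overrides$seed <- as.integer(flags$seed)
  if (!is.null(flags$motion)) overrides$motion <- flags$motion
  if (!is.null(flags$out)) overrides$out_dir <- flags$out
  cfg <- read_run_config(flags$config, overrides)
  switch(cmd,
    simulate = run_simulate(cfg),
    fit = run_fit(cfg),
    validate = run_validate(cfg),
    report = { run_simulate(cfg); run_fit(cfg); run_validate(cfg) },
    stop("unknown subcommand '", cmd, "'\n", usage))
  invisible(0L)
}
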