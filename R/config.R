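# Configuration parsing and result serialization (YAML in, CSV/JSON out).

config_defaults <- function() {
  list(
    stimuli = list(task = "II", mean_A = NULL, mean_B = NULL,
                   cov_A = NULL, cov_B = NULL,
                   perceptual_noise_sd = 4, criterial_noise_sd = 2),
    cortex = as.list(.striat$cortex[c("n_rows", "n_cols", "height",
                                      "spread")]),
    network = .striat$network,
    traces = .striat$traces,
    reward = .striat$reward,
    plasticity = .striat$plasticity,
    experiment = list(delay_ms = 500, delay_mean_ms = NULL, delay_sd_ms = 0,
                      n_blocks = 5,
                      trials_per_block = .striat$experiment$trials_per_block,
                      n_replications = .striat$experiment$n_replications,
                      mixture_counts = c(15, 4, 1)),
    master_seed = 1L,
    output_dir = "results"
  )
}

merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", section, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown key(s) in config section '", section, "': ",
         paste(unknown, collapse = ", "))
  # assign via list() so explicit nulls survive (modifyList would drop them)
  for (k in names(user)) defaults[k] <- list(user[[k]])
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML file with optional sections `stimuli`, `cortex`, `network`,
#' `traces`, `reward`, `plasticity`, `experiment` plus `master_seed` and
#' `output_dir`, fills in all documented defaults, rejects unknown keys and
#' validates cross-field constraints (`theta_NMDA > theta_AMPA`,
#' nonnegative delays and noise).
#'
#' @param path Path to a YAML config, or `NULL` for all defaults.
#' @return A validated config list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    top_unknown <- setdiff(names(user), names(cfg))
    if (length(top_unknown))
      stop("unknown top-level config key(s): ",
           paste(top_unknown, collapse = ", "))
    for (sec in intersect(names(user), names(cfg))) {
      if (sec %in% c("master_seed", "output_dir"))
        cfg[[sec]] <- user[[sec]]
      else
        cfg[[sec]] <- merge_section(cfg[[sec]], user[[sec]], sec)
    }
  }
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  p <- cfg$plasticity
  if (!(p$theta_NMDA > p$theta_AMPA))
    stop("config: plasticity$theta_NMDA must exceed plasticity$theta_AMPA")
  if (cfg$network$sigma_C < 0) stop("config: network$sigma_C must be >= 0")
  e <- cfg$experiment
  if (!is.null(e$delay_ms) && e$delay_ms < 0)
    stop("config: experiment$delay_ms must be >= 0")
  if (!is.null(e$delay_sd_ms) && e$delay_sd_ms < 0)
    stop("config: experiment$delay_sd_ms must be >= 0")
  if (!cfg$stimuli$task %in% c("II", "RB"))
    stop("config: stimuli$task must be 'II' or 'RB'")
  invisible(cfg)
}

#' Build a condition spec from a config
#'
#' @param cfg A `run_config` from [load_config()].
#' @return A [condition_spec()].
#' @export
config_condition <- function(cfg) {
  e <- cfg$experiment
  condition_spec(task = cfg$stimuli$task, delay_ms = e$delay_ms,
                 delay_mean_ms = e$delay_mean_ms,
                 delay_sd_ms = if (is.null(e$delay_sd_ms)) 0 else e$delay_sd_ms,
                 n_blocks = e$n_blocks,
                 trials_per_block = e$trials_per_block,
                 sigma_C = cfg$network$sigma_C,
                 n_replications = e$n_replications,
                 seed = cfg$master_seed)
}

#' Write simulation results and a run manifest
#'
#' Writes `curves.csv` (condition, block, mean, sd, se), `trials.csv`
#' (per-trial records, when present), optional `weights_final.csv`, and
#' `manifest.json` holding the seed, package version and a hash of the
#' effective parameters, so any result is regenerable from its manifest.
#'
#' @param curves A `learning_curve` or named list of them.
#' @param path Output directory (created if missing).
#' @param config Optional `run_config` echoed into the manifest.
#' @param weights Optional final weight matrix.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(curves, path, config = NULL, weights = NULL) {
  if (inherits(curves, "learning_curve")) curves <- list(run = curves)
  stopifnot(length(curves) >= 1)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  curve_df <- do.call(rbind, lapply(names(curves), function(nm) {
    cbind(condition = nm, curves[[nm]]$curve)
  }))
  f <- file.path(path, "curves.csv")
  write.csv(curve_df, f, row.names = FALSE)
  files <- c(files, f)

  trials <- do.call(rbind, lapply(names(curves), function(nm) {
    tr <- curves[[nm]]$trials
    if (is.null(tr)) NULL else cbind(condition = nm, tr)
  }))
  if (!is.null(trials)) {
    f <- file.path(path, "trials.csv")
    write.csv(trials, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(weights)) {
    f <- file.path(path, "weights_final.csv")
    write_weights_csv(weights, f)
    files <- c(files, f)
  }

  params <- if (is.null(config)) config_defaults() else unclass(config)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(params, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package = "striatlearn",
    version = as.character(utils::packageVersion("striatlearn")),
    seed = params$master_seed,
    parameter_hash = unname(tools::md5sum(tmp)),
    parameters = params,
    conditions = names(curves),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE))
  f <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
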