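## Study orchestration: configuration files, validation, end-to-end runs.
## The command-line entry point in inst/cli/cuffmc is a thin wrapper over
## these functions.

#' Read a study configuration file
#'
#' YAML study configuration; missing fields take the defaults of
#' [study_config()].
#'
#' @param path YAML file path.
#' @return A `cuffmc_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

#' Validate study configuration and species fixtures without simulating
#'
#' Checks the configuration schema, loads and validates every referenced
#' species parameter set, and smoke-builds the fixtures (postures, bone
#' geometry, model geometry) for each species and instance.
#'
#' @param config A `cuffmc_config` (or path to one).
#' @return Invisibly, a list of validated species sets; errors name the
#'   offending field.
#' @export
validate_study_config <- function(config = study_config()) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "cuffmc_config"))
  if (!all(config$species %in% c("human", "chimpanzee"))) {
    stop("config$species must be a subset of human/chimpanzee", call. = FALSE)
  }
  if (!all(config$instances %in% .instances)) {
    stop("config$instances contains an unknown support instance", call. = FALSE)
  }
  if (config$n_iterations < 1) stop("config$n_iterations must be >= 1", call. = FALSE)
  if (config$sigma_max <= 0) stop("config$sigma_max must be > 0", call. = FALSE)
  if (!config$objective_exponent %in% c(2, 3)) {
    stop("config$objective_exponent must be 2 or 3", call. = FALSE)
  }
  sets <- lapply(config$species, function(s) {
    load_species(config$species_paths[[s]] %||% species_config_path(s))
  })
  names(sets) <- config$species
  for (sp in sets) {
    for (inst in config$instances) {
      posture <- generate_posture(inst, sp, config$seed)
      stopifnot(posture$humerothoracic_elevation > 100)
      invisible(build_model_geometry(sp, posture))
    }
  }
  invisible(sets)
}

#' Run the full study end to end and write all artifacts
#'
#' Validates the configuration, runs the Monte Carlo analysis suite, and
#' renders figures, tables, the overlap report and the run manifest into
#' `out_dir`. Every artifact is regenerable from (configuration, seed)
#' alone.
#'
#' @param config A `cuffmc_config` or path to a YAML configuration.
#' @param out_dir Output directory.
#' @param figures Write PNG figures?
#' @return The `cuffmc_suite`, invisibly; written paths in attribute
#'   `"paths"`.
#' @export
run_study <- function(config = study_config(), out_dir = "cuffmc_results",
                      figures = TRUE) {
  if (is.character(config)) config <- read_study_config(config)
  sets <- validate_study_config(config)
  suite <- run_analysis_suite(config, species_sets = sets)
  paths <- render_reports(suite, out_dir, figures = figures)
  pattern_summary(suite)
  attr(suite, "paths") <- paths
  invisible(suite)
}
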