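# Study configuration and result serialization. The config is a plain
# nested list, round-tripping losslessly through YAML; every default is
# documented at its defining function (cohort, generator, dynamics, knee
# load, geometry, connectors, biphasic column).

#' Default study configuration
#'
#' The emulated study design: 7 participants, 5 trials per style, four gait
#' styles, four strength conditions (reference plus a uniform 40% isometric
#' strength reduction of the knee extensors, hip abductors and ankle
#' extensors separately). The contact foundation modulus is calibrated from
#' the biphasic column at the gait loading timescale unless a fixed
#' `modulus` is given under `contact`.
#'
#' @return nested named list
#' @export
default_study_config <- function() {
  list(
    n_participants = 7L,
    n_trials = 5L,
    styles = GAIT_STYLES,
    master_seed = 0L,
    strength_fraction = 0.40,
    strength_groups = c("knee_extensor", "hip_abductor", "ankle_extensor"),
    cohort = default_cohort_params(),
    generator = default_generator_params(),
    dynamics = default_dynamics_params(),
    dynamics_mode = "quasi_static",
    kneeload = default_kneeload_params(),
    reference_model = list(mass = 75, height = 1.75, fat_fraction = 0.20,
                           arm_cosine_modulation = FALSE),
    recruitment = list(tol = 1e-8, order = 3),
    contact = list(
      nx = 8L, nz = 8L, plate_x = 0.020, plate_z = 0.015,
      spacing = 0.040, thickness = 0.003, poisson = 0.42,
      condyle_rx = 0.035, condyle_rz = 0.045,
      dish_rx = 0.055, dish_rz = 0.070,
      modulus = NULL, # NULL: calibrate from the biphasic column
      loading_timescale = 0.5
    ),
    connectors = list(tf_translation = 0.5, tf_rotation = 1.2,
                      patellar_translation = 0.2, patellar_rotation = 0.9),
    cartilage = list(thickness = 0.003, aggregate_modulus = 0.5e6,
                     permeability = 2e-15, n_nodes = 100L),
    percent_change_floor = 0.01,
    late_stance_window = c(70, 90)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, "$", key)
    if (!key %in% names(defaults)) {
      stop_gaitsens("gaitsens_invalid_configuration",
                    sprintf("unknown configuration key '%s'", full))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      val <- user[[key]]
      # YAML maps come back as lists; named atomic defaults keep their type
      if (is.atomic(defaults[[key]]) && is.list(val)) val <- unlist(val)
      if (is.integer(defaults[[key]]) && is.numeric(val) &&
          all(val == round(val))) val <- as.integer(val)
      defaults[[key]] <- val
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (cfg$n_participants < 1 || cfg$n_trials < 1) {
    stop_gaitsens("gaitsens_invalid_configuration",
                  "n_participants and n_trials must be >= 1")
  }
  if (!all(cfg$styles %in% GAIT_STYLES)) {
    stop_gaitsens("gaitsens_invalid_configuration", "unknown gait style in config")
  }
  if (!is.finite(cfg$strength_fraction) ||
      cfg$strength_fraction < 0 || cfg$strength_fraction >= 1) {
    stop_gaitsens("gaitsens_invalid_configuration",
                  "strength_fraction must lie in [0, 1)")
  }
  if (!all(cfg$strength_groups %in% MUSCLE_GROUPS)) {
    stop_gaitsens("gaitsens_invalid_configuration", "unknown muscle group in config")
  }
  cfg
}

#' Load a study configuration file
#'
#' YAML with any subset of the keys of [default_study_config()]; missing
#' keys take their defaults, unknown keys are rejected by name. An empty
#' file yields the full default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults
#' @return validated configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_study_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop_gaitsens("gaitsens_io", sprintf("config file not found: %s", path))
    }
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
}

#' Save a study configuration to YAML
#' @param config configuration list
#' @param path output path
#' @export
save_config <- function(config, path) {
  # named atomic vectors must become YAML maps, or their names are lost
  yamlify <- function(x) {
    if (is.list(x)) lapply(x, yamlify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(yamlify(config), path, precision = 17)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

write_csv_exact <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write study results to a directory
#'
#' Tidy CSV tables (stress summaries, percent-change and percentage-point
#' curves, peaks, speeds, test results) plus `manifest.yaml` recording the
#' config hash, the master seed, per-participant seeds and the failure log.
#' Overwrites idempotently: identical results give byte-identical files.
#'
#' @param results a `study_result` from [run_study()]
#' @param out_dir output directory (created if missing)
#' @return the manifest, invisibly
#' @export
write_results <- function(results, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop_gaitsens("gaitsens_io", sprintf("cannot create output directory %s", out_dir))
  }
  tabs <- c("stress", "percent_change", "pp_difference", "peaks", "speeds",
            "late_stance")
  for (tb in tabs) {
    write_csv_exact(results[[tb]], file.path(out_dir, paste0(tb, ".csv")))
  }
  write_csv_exact(results$tests$peak_paired_t, file.path(out_dir, "peak_tests.csv"))
  write_csv_exact(speed_summary(results$speeds), file.path(out_dir, "speed_summary.csv"))
  save_config(results$config, file.path(out_dir, "config.yaml"))
  manifest <- list(
    config_hash = results$manifest$config_hash,
    master_seed = results$manifest$master_seed,
    participant_seeds = results$manifest$participant_seeds,
    n_cells = results$manifest$n_cells,
    failures = results$manifest$failures,
    created_by = "gaitsens"
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"), precision = 17)
  invisible(manifest)
}
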