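# GaitTrial container: stance-phase-normalized kinematics + ground reaction
# data for one trial. Coordinates: x anterior, y up, z lateral (right leg);
# the ankle's ground projection sits at x = 0, z = step_width / 2.

ANGLE_COLS <- c("hip_flex", "hip_add", "hip_rot", "knee_flex", "ankle_pf", "ankle_inv")
GRF_COLS <- c("grf_x", "grf_y", "grf_z")
COP_COLS <- c("cop_x", "cop_z")
GAIT_STYLES <- c("normal", "toe_out", "toe_in", "wide")

#' Construct and validate a stance-phase gait trial
#'
#' @param participant_id label of the participant the trial belongs to
#' @param style one of `"normal"`, `"toe_out"`, `"toe_in"`, `"wide"`
#' @param phase_grid percent-of-stance samples, strictly increasing 0 to 100
#' @param joint_angles matrix (samples x 6) with columns
#'   `hip_flex, hip_add, hip_rot, knee_flex, ankle_pf, ankle_inv`, degrees
#' @param grf matrix (samples x 3) ground reaction force, N, columns
#'   `grf_x, grf_y, grf_z`; `grf_y` is vertical and must be >= 0 with zero
#'   endpoints (heel strike / toe off)
#' @param cop matrix (samples x 2) centre of pressure, m, columns
#'   `cop_x, cop_z`
#' @param foot_progression_angle degrees, positive = toe-out
#' @param step_width m
#' @param speed walking speed, m/s
#' @param stance_time stance duration, s
#' @param trial_index integer trial number within (participant, style)
#' @param seed integer seed the trial was generated from
#' @return object of class `gait_trial`
#' @export
gait_trial <- function(participant_id, style, phase_grid, joint_angles, grf, cop,
                       foot_progression_angle, step_width, speed, stance_time,
                       trial_index = 1L, seed = NA_integer_) {
  style <- match.arg(style, GAIT_STYLES)
  joint_angles <- as.matrix(joint_angles)
  grf <- as.matrix(grf)
  cop <- as.matrix(cop)
  colnames(joint_angles) <- ANGLE_COLS
  colnames(grf) <- GRF_COLS
  colnames(cop) <- COP_COLS
  x <- structure(
    list(participant_id = participant_id, style = style,
         phase_grid = as.numeric(phase_grid),
         joint_angles = joint_angles, grf = grf, cop = cop,
         foot_progression_angle = foot_progression_angle,
         step_width = step_width, speed = speed, stance_time = stance_time,
         trial_index = as.integer(trial_index), seed = seed),
    class = "gait_trial"
  )
  validate_gait_trial(x)
  x
}

#' Validate the invariants of a gait trial
#'
#' Checks the grid, vertical-force non-negativity and zero endpoints, and the
#' knee-flexion range; errors on violation, returns the trial invisibly.
#' @param x a `gait_trial`
#' @export
validate_gait_trial <- function(x) {
  g <- x$phase_grid
  n <- length(g)
  if (n < 3 || g[1] != 0 || g[n] != 100 || any(diff(g) <= 0)) {
    stop_gaitsens("gaitsens_invalid_input", "phase_grid must increase strictly from 0 to 100")
  }
  dims_ok <- nrow(x$joint_angles) == n && nrow(x$grf) == n && nrow(x$cop) == n
  if (!dims_ok) stop_gaitsens("gaitsens_invalid_input", "waveform row counts must match phase_grid")
  if (any(!is.finite(x$joint_angles)) || any(!is.finite(x$grf)) || any(!is.finite(x$cop))) {
    stop_gaitsens("gaitsens_invalid_input", "non-finite waveform values")
  }
  fy <- x$grf[, "grf_y"]
  if (any(fy < 0)) stop_gaitsens("gaitsens_invalid_input", "vertical GRF must be >= 0")
  if (fy[1] != 0 || fy[n] != 0) {
    stop_gaitsens("gaitsens_invalid_input", "vertical GRF must vanish at heel strike and toe off")
  }
  kf <- x$joint_angles[, "knee_flex"]
  if (any(kf < 0) || any(kf > 90)) {
    stop_gaitsens("gaitsens_invalid_input", "knee flexion must stay within [0, 90] degrees")
  }
  if (!is.finite(x$speed) || x$speed <= 0 || !is.finite(x$stance_time) || x$stance_time <= 0) {
    stop_gaitsens("gaitsens_invalid_input", "speed and stance_time must be positive")
  }
  invisible(x)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial %s/%s #%d>  %d samples, speed %.2f m/s, FPA %+.1f deg, step width %.3f m\n",
    x$participant_id, x$style, x$trial_index, length(x$phase_grid),
    x$speed, x$foot_progression_angle, x$step_width))
  invisible(x)
}

#' Write a gait trial to CSV
#'
#' Column layout:
#' `phase,hip_flex,hip_add,hip_rot,knee_flex,ankle_pf,ankle_inv,grf_x,grf_y,grf_z,cop_x,cop_z`
#' (angles deg, forces N, CoP m). Scalar metadata (style, speed, seed, ...)
#' go to a YAML sidecar `<path>.meta.yaml`.
#'
#' @param trial a `gait_trial`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_gait_trial <- function(trial, path) {
  df <- data.frame(phase = trial$phase_grid, trial$joint_angles, trial$grf, trial$cop)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(
    participant_id = trial$participant_id, style = trial$style,
    trial_index = trial$trial_index,
    foot_progression_angle = trial$foot_progression_angle,
    step_width = trial$step_width, speed = trial$speed,
    stance_time = trial$stance_time, seed = trial$seed
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 17)
  invisible(path)
}

#' Read a gait trial written by [write_gait_trial()]
#'
#' @param path CSV path (expects the `<path>.meta.yaml` sidecar next to it)
#' @return a `gait_trial`
#' @export
read_gait_trial <- function(path) {
  df <- utils::read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  gait_trial(
    participant_id = meta$participant_id, style = meta$style,
    phase_grid = df$phase,
    joint_angles = as.matrix(df[, ANGLE_COLS]),
    grf = as.matrix(df[, GRF_COLS]),
    cop = as.matrix(df[, COP_COLS]),
    foot_progression_angle = meta$foot_progression_angle,
    step_width = meta$step_width, speed = meta$speed,
    stance_time = meta$stance_time,
    trial_index = meta$trial_index,
    seed = if (is.null(meta$seed)) NA_integer_ else meta$seed
  )
}
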