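# Assembly of the twelve musculoskeletal outputs handed to the contact
# stage: knee flexion angle, tibiofemoral forces (3), tibiofemoral abduction
# and axial-rotation moments, patellofemoral forces (3) and moments (3).
# Axes follow the knee coordinate system: +x posterior, +y upward, +z
# lateral. Axial tf force is stored negative in compression.

#' Default knee-load assembly parameters
#'
#' The patellofemoral pulley ratio maps the quadriceps resultant to the
#' patellofemoral compression force; it rises linearly from `ratio_20` at
#' 20 degrees of knee flexion to `ratio_60` at 60 degrees (clamped outside).
#' @return named list
#' @export
default_kneeload_params <- function() {
  list(pf_ratio_angles = c(20, 60), pf_ratio_values = c(0.7, 1.0))
}

pf_pulley_ratio <- function(flexion_deg, params = default_kneeload_params()) {
  a <- params$pf_ratio_angles; v <- params$pf_ratio_values
  frac <- (pmin(pmax(flexion_deg, a[1]), a[2]) - a[1]) / (a[2] - a[1])
  v[1] + frac * (v[2] - v[1])
}

#' Assemble knee loading from dynamics and muscle forces
#'
#' The axial tibiofemoral force adds, to the axial component of the
#' intersegmental knee force, every knee-crossing muscle force weighted by
#' its compression fraction (cosine of its line of action to the tibial
#' axis). The abduction moment is the frontal-plane net knee moment (the
#' default roster has no knee-crossing frontal arms to subtract). The
#' patellofemoral force is the quadriceps resultant through the
#' flexion-angle-dependent pulley ratio.
#'
#' @param trial a [gait_trial()]
#' @param loads the matching `net_loads`
#' @param forces the matching `recruitment_trace`
#' @param model the `msk_model` used for recruitment
#' @param params see [default_kneeload_params()]
#' @param meta optional named list (participant, style, condition) carried on
#'   the trace
#' @return object of class `knee_load_trace`
#' @export
assemble_knee_loads <- function(trial, loads, forces, model,
                                params = default_kneeload_params(), meta = list()) {
  n <- length(loads$phase_grid)
  if (nrow(forces$forces) != n || length(trial$phase_grid) != n) {
    stop_gaitsens("gaitsens_invalid_input", "trial, loads and forces must share one grid")
  }
  if (length(forces$failures) > 0) {
    idx <- forces$failures[[1]]$sample
    stop_gaitsens("gaitsens_invalid_input",
                  sprintf("missing muscle-force sample %d (%s)", idx,
                          forces$failures[[1]]$class))
  }
  fmat <- forces$forces
  crossing <- vapply(model$muscles, `[[`, TRUE, "crosses_knee")
  cfrac <- vapply(model$muscles, `[[`, 0, "compression_fraction")
  muscle_comp <- as.numeric(fmat[, crossing, drop = FALSE] %*% cfrac[crossing])

  # intersegmental axial component along the tibial axis (positive = the
  # femur pressing down the tibia)
  inter_axial <- abs(rowSums(loads$forces$knee * loads$shank_axis))
  axial <- inter_axial + muscle_comp

  tf_force <- cbind(
    x = -loads$forces$knee[, 1], # AP shear handed to the femur (+x posterior)
    y = -axial,                  # compression, negative by convention
    z = loads$forces$knee[, 3]
  )

  quads <- vapply(model$muscles, function(mu) mu$group == "knee_extensor", TRUE)
  q_res <- rowSums(fmat[, quads, drop = FALSE])
  pf_mag <- q_res * pf_pulley_ratio(trial$joint_angles[, "knee_flex"], params)
  pf_force <- cbind(x = -pf_mag, y = 0 * pf_mag, z = 0 * pf_mag)
  pf_moment <- cbind(x = 0 * pf_mag, y = 0 * pf_mag, z = 0 * pf_mag)

  structure(
    list(phase_grid = loads$phase_grid,
         knee_flexion_angle = trial$joint_angles[, "knee_flex"],
         tf_force = tf_force,
         tf_abduction_moment = -loads$knee_adduction_moment_ext,
         tf_rotation_moment = loads$knee_rotation_moment,
         pf_force = pf_force, pf_moment = pf_moment,
         meta = meta),
    class = "knee_load_trace"
  )
}

#' Pointwise average of knee load traces
#'
#' Used to average the five gait trials of one style before the contact
#' solve. All traces must share the phase grid and (participant, style,
#' condition) metadata.
#'
#' @param traces list of `knee_load_trace`
#' @return a `knee_load_trace`
#' @export
average_traces <- function(traces) {
  stopifnot(length(traces) >= 1)
  ref <- traces[[1]]
  for (tr in traces[-1]) {
    if (!identical(tr$phase_grid, ref$phase_grid)) {
      stop_gaitsens("gaitsens_invalid_input", "traces must share an identical phase grid")
    }
    if (!identical(tr$meta[c("participant", "style", "condition")],
                   ref$meta[c("participant", "style", "condition")])) {
      stop_gaitsens("gaitsens_invalid_input",
                    "cannot average traces from mixed styles or conditions")
    }
  }
  avg <- ref
  for (fld in c("knee_flexion_angle", "tf_force", "tf_abduction_moment",
                "tf_rotation_moment", "pf_force", "pf_moment")) {
    acc <- Reduce(`+`, lapply(traces, `[[`, fld))
    avg[[fld]] <- acc / length(traces)
  }
  avg
}

#' @export
print.knee_load_trace <- function(x, ...) {
  cat(sprintf("<knee_load_trace>  %d samples; peak compression %.0f N, peak |abd moment| %.1f N m\n",
              length(x$phase_grid), max(-x$tf_force[, "y"]),
              max(abs(x$tf_abduction_moment))))
  invisible(x)
}
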