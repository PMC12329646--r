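# Quasi-static (optionally inertial) bottom-up inverse dynamics of the
# stance limb, solved as two planar problems (sagittal x-y, frontal z-y)
# sharing the vertical force. The transverse hip rotation demand is a
# configurable fraction of the frontal hip moment.
#
# Kinematic chain conventions (right leg, x anterior, y up, z lateral):
#   - ankle joint centre at x = 0, z = step_width / 2, y = ankle_height;
#   - sagittal tilts from the vertical: thigh = hip flexion, shank =
#     hip flexion - knee flexion (positive tilt leans the segment's proximal
#     end posterior, i.e. the limb reaches forward);
#   - frontal: the shank tilts by half the ankle inversion angle; the hip is
#     anchored laterally at `hip_offset` (the pelvis riding over the stance
#     foot), which is what gives the stance-phase hip abduction demand in a
#     single-limb model.
#
# Internal net moment conventions (the recruitment right-hand side):
#   hip_flex+ = flexion, hip_add+ = adduction, hip_rot+ = internal rotation,
#   knee_flex+ = flexion, ankle_pf+ = plantarflexion, ankle_inv+ = inversion.

#' Default inverse-dynamics parameters
#' @return named list: ankle height (m), lateral hip anchor (m), transverse
#'   moment fraction, gravity (m/s^2)
#' @export
default_dynamics_params <- function() {
  list(ankle_height = 0.039 * 1.75, hip_offset = 0.09,
       rotation_fraction = 0.1, gravity = 9.81)
}

#' Net joint loads over stance from a gait trial and a scaled model
#'
#' Bottom-up foot-to-hip recursion. In `quasi_static` mode (the study
#' default) each joint's internal net moment balances the ground reaction
#' force and segment gravity distal to it; `inertial` mode adds segment
#' translational and sagittal rotational inertia from finite-differenced
#' kinematics.
#'
#' @param trial a [gait_trial()]
#' @param model an `msk_model` scaled to the same participant
#' @param mode `"quasi_static"` (default) or `"inertial"`
#' @param params see [default_dynamics_params()]
#' @return object of class `net_loads`: per-sample internal net moments for
#'   the six modeled DoFs, intersegmental forces per joint, the knee frontal
#'   external adduction moment, knee rotation moment, and the shank axis
#' @export
inverse_dynamics <- function(trial, model, mode = c("quasi_static", "inertial"),
                             params = default_dynamics_params()) {
  mode <- match.arg(mode)
  validate_gait_trial(trial)
  n <- length(trial$phase_grid)
  deg <- pi / 180
  g <- params$gravity

  hf <- trial$joint_angles[, "hip_flex"] * deg
  kf <- trial$joint_angles[, "knee_flex"] * deg
  ai <- trial$joint_angles[, "ankle_inv"] * deg
  beta <- hf - kf # shank sagittal tilt

  L_sh <- model$segments$shank$length
  L_th <- model$segments$thigh$length
  L_ft <- model$segments$foot$length

  ankle <- cbind(x = rep(0, n), y = rep(params$ankle_height, n),
                 z = rep(trial$step_width / 2, n))
  knee <- ankle + cbind(-L_sh * sin(beta), L_sh * cos(beta), L_sh * sin(ai / 2))
  hip <- knee + cbind(-L_th * sin(hf), L_th * cos(hf), 0)
  hip[, 3] <- params$hip_offset

  com <- list(
    foot = cbind(0.25 * L_ft, pmin(ankle[, 2], 0.02), ankle[, 3]),
    shank = knee + model$segments$shank$com_fraction * (ankle - knee),
    thigh = hip + model$segments$thigh$com_fraction * (knee - hip)
  )
  seg_mass <- c(foot = model$segments$foot$mass,
                shank = model$segments$shank$mass,
                thigh = model$segments$thigh$mass)

  grf <- trial$grf
  cop <- cbind(trial$cop[, "cop_x"], 0, trial$cop[, "cop_z"])

  # inertial terms: segment COM accelerations and sagittal angular
  # accelerations by central differences on the phase grid scaled by the
  # stance duration
  inert_force <- lapply(seg_mass, function(m) matrix(0, n, 3))
  inert_moment_z <- stats::setNames(rep(list(numeric(n)), 3), names(seg_mass))
  if (mode == "inertial") {
    dt <- trial$stance_time / (n - 1)
    accel <- function(x) {
      a <- matrix(0, nrow(x), ncol(x))
      if (nrow(x) >= 3) {
        i <- 2:(nrow(x) - 1)
        a[i, ] <- (x[i + 1, , drop = FALSE] - 2 * x[i, , drop = FALSE] +
                     x[i - 1, , drop = FALSE]) / dt^2
        a[1, ] <- a[2, ]; a[nrow(x), ] <- a[nrow(x) - 1, ]
      }
      a
    }
    seg_angle <- list(foot = rep(0, n), shank = beta, thigh = hf)
    for (s in names(seg_mass)) {
      inert_force[[s]] <- seg_mass[[s]] * accel(com[[s]])
      L <- switch(s, foot = L_ft, shank = L_sh, thigh = L_th)
      I <- seg_mass[[s]] * (0.302 * L)^2
      alpha <- as.numeric(accel(cbind(seg_angle[[s]], 0, 0))[, 1])
      inert_moment_z[[s]] <- I * alpha
    }
  }

  cross3 <- function(r, f) {
    cbind(r[, 2] * f[, 3] - r[, 3] * f[, 2],
          r[, 3] * f[, 1] - r[, 1] * f[, 3],
          r[, 1] * f[, 2] - r[, 2] * f[, 1])
  }

  # external + gravity + inertial load moment about a joint, from the distal
  # free body; returns list(moment n x 3, force n x 3)
  distal_load <- function(joint_pos, segs) {
    Fm <- cross3(cop - joint_pos, grf)
    Ff <- grf
    for (s in segs) {
      w <- cbind(0, -seg_mass[[s]] * g, 0) [rep(1, n), , drop = FALSE]
      fi <- -inert_force[[s]] # d'Alembert force
      Fm <- Fm + cross3(com[[s]] - joint_pos, w + fi)
      Fm[, 3] <- Fm[, 3] - inert_moment_z[[s]]
      Ff <- Ff + w + fi
    }
    list(moment = Fm, force = Ff)
  }

  la <- distal_load(ankle, "foot")
  lk <- distal_load(knee, c("foot", "shank"))
  lh <- distal_load(hip, c("foot", "shank", "thigh"))

  # internal net muscle demands M_int = -M_ext, mapped onto the DoF sign
  # conventions (+z internal moment = hip flexion / knee extension / ankle
  # dorsiflexion; +x internal = hip adduction / ankle eversion)
  moments <- cbind(
    hip_flex = -lh$moment[, 3],
    hip_add = -lh$moment[, 1],
    hip_rot = -params$rotation_fraction * lh$moment[, 1],
    knee_flex = lk$moment[, 3],
    ankle_pf = la$moment[, 3],
    ankle_inv = la$moment[, 1]
  )

  # intersegmental force = force the proximal segment applies to the distal
  # chain (balances GRF + gravity + inertia)
  forces <- list(hip = -lh$force, knee = -lk$force, ankle = -la$force)

  shank_axis <- cbind(-sin(beta), cos(beta), sin(ai / 2))
  shank_axis <- shank_axis / sqrt(rowSums(shank_axis^2))

  structure(
    list(phase_grid = trial$phase_grid, moments = moments, forces = forces,
         knee_adduction_moment_ext = lk$moment[, 1],
         knee_rotation_moment = params$rotation_fraction * lk$moment[, 1],
         shank_axis = shank_axis, joints = list(ankle = ankle, knee = knee, hip = hip),
         mode = mode, stance_time = trial$stance_time),
    class = "net_loads"
  )
}

#' @export
print.net_loads <- function(x, ...) {
  cat(sprintf("<net_loads>  %d samples (%s); peak |knee flex demand| %.1f N m\n",
              length(x$phase_grid), x$mode, max(abs(x$moments[, "knee_flex"]))))
  invisible(x)
}

#' Write net joint loads to CSV
#' @param loads a `net_loads`
#' @param path output path
#' @export
write_net_loads <- function(loads, path) {
  df <- data.frame(phase = loads$phase_grid, loads$moments,
                   knee_adduction_moment_ext = loads$knee_adduction_moment_ext)
  for (j in names(loads$forces)) {
    f <- loads$forces[[j]]
    colnames(f) <- paste0(j, c("_fx", "_fy", "_fz"))
    df <- cbind(df, f)
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
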