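# Simplified lower-limb musculoskeletal model: three segments (thigh, shank,
# foot), six joint DoFs (hip flex/add/rot, knee flex, ankle pf/inv), and a
# roster of Hill-type-strength muscle-tendon units with constant (optionally
# angle-modulated) moment arms. Anatomy is a minimal planar-pair layout:
# sagittal arms for flexor/extensor groups, frontal arms for ab-/adductors,
# and a small stabilizer pair on hip internal rotation. Strength enters only
# as the isometric capacity N_i normalizing the recruitment criterion.

MUSCLE_GROUPS <- c("knee_extensor", "knee_flexor", "hip_abductor", "hip_adductor",
                   "ankle_extensor", "ankle_dorsiflexor", "hip_flexor", "hip_extensor")
JOINT_DOFS <- c("hip_flex", "hip_add", "hip_rot", "knee_flex", "ankle_pf", "ankle_inv")

# Default roster. Moment arms in m, signed by DoF convention (positive arm =
# the muscle produces a positive moment about that DoF: hip flexion+, hip
# adduction+, internal rotation+, knee flexion+, ankle plantarflexion+,
# inversion+). Strengths are order-of-magnitude physiological defaults.
# compression_fraction: cosine of the unit's line-of-action angle to the
# tibial axis, used when summing knee-crossing forces into joint compression.
default_muscle_table <- function() {
  m <- function(name, group, strength, arms, crosses_knee = FALSE, compression = 0.95) {
    list(name = name, group = group, isometric_strength = strength,
         moment_arms = arms, crosses_knee = crosses_knee,
         compression_fraction = compression)
  }
  list(
    m("rectus_femoris", "knee_extensor", 1200,
      c(hip_flex = 0.035, knee_flex = -0.045), TRUE, 0.95),
    m("vastus_lateralis", "knee_extensor", 2800, c(knee_flex = -0.045), TRUE, 0.97),
    m("vastus_medialis", "knee_extensor", 2300, c(knee_flex = -0.045), TRUE, 0.97),
    m("vastus_intermedius", "knee_extensor", 1800, c(knee_flex = -0.045), TRUE, 0.97),
    m("gluteus_medius", "hip_abductor", 1800, c(hip_add = -0.055, hip_rot = 0.010)),
    m("gluteus_minimus", "hip_abductor", 600, c(hip_add = -0.045, hip_rot = 0.008)),
    m("tensor_fasciae_latae", "hip_abductor", 700,
      c(hip_add = -0.045, hip_flex = 0.030, hip_rot = 0.012)),
    m("gastrocnemius", "ankle_extensor", 2500,
      c(ankle_pf = 0.045, knee_flex = 0.020), TRUE, 0.95),
    m("soleus", "ankle_extensor", 3500, c(ankle_pf = 0.040)),
    m("biceps_femoris", "knee_flexor", 1300,
      c(knee_flex = 0.030, hip_flex = -0.055), TRUE, 0.92),
    m("semitendinosus", "knee_flexor", 1000,
      c(knee_flex = 0.035, hip_flex = -0.060), TRUE, 0.92),
    m("gluteus_maximus", "hip_extensor", 2500, c(hip_flex = -0.060, hip_rot = -0.020)),
    m("iliopsoas", "hip_flexor", 2000, c(hip_flex = 0.035)),
    m("adductor_longus", "hip_adductor", 800, c(hip_add = 0.045, hip_flex = 0.010)),
    m("adductor_magnus", "hip_adductor", 1500, c(hip_add = 0.055, hip_flex = -0.010)),
    m("tibialis_anterior", "ankle_dorsiflexor", 1000,
      c(ankle_pf = -0.035, ankle_inv = 0.025)),
    m("peroneus_tertius", "ankle_dorsiflexor", 400,
      c(ankle_pf = -0.025, ankle_inv = -0.025))
  )
}

#' Reference lower-limb musculoskeletal model
#'
#' Builds the unscaled reference model: segment masses as standard fractions
#' of body mass (thigh 0.10, shank 0.0465, foot 0.0145 per side), COM at
#' standard proximal fractions of segment length, and the default 17-unit
#' muscle roster covering all eight functional groups.
#'
#' @param mass reference body mass, kg
#' @param height reference stature, m
#' @param fat_fraction reference body-fat fraction
#' @param muscles muscle roster (list as from `default_muscle_table()`)
#' @param arm_cosine_modulation logical; if TRUE moment arms are modulated by
#'   the cosine of half the joint angle (flat near neutral posture)
#' @return object of class `msk_model`
#' @export
reference_model <- function(mass = 75, height = 1.75, fat_fraction = 0.20,
                            muscles = default_muscle_table(),
                            arm_cosine_modulation = FALSE) {
  segf <- c(thigh = 0.245, shank = 0.246, foot = 0.152)
  lengths <- segf * height
  segments <- list(
    thigh = list(mass = 0.100 * mass, length = lengths[["thigh"]],
                 com_fraction = 0.433),
    shank = list(mass = 0.0465 * mass, length = lengths[["shank"]],
                 com_fraction = 0.433),
    foot = list(mass = 0.0145 * mass, length = lengths[["foot"]],
                com_fraction = 0.50)
  )
  model <- structure(
    list(participant_id = "reference", mass = mass, height = height,
         fat_fraction = fat_fraction, lean_mass = mass * (1 - fat_fraction),
         segments = segments, joint_dofs = JOINT_DOFS, muscles = muscles,
         arm_cosine_modulation = arm_cosine_modulation),
    class = "msk_model"
  )
  validate_msk_model(model)
  model
}

#' Validate a musculoskeletal model
#'
#' Checks positive strengths, arm magnitudes (<= 0.15 m), that every unit
#' actuates at least one DoF, and the bidirectional-actuation invariant:
#' every joint DoF has at least one muscle with a positive and one with a
#' negative arm, so the recruitment problem is feasible in both directions.
#' @param model an `msk_model`
#' @export
validate_msk_model <- function(model) {
  for (mu in model$muscles) {
    if (!is.finite(mu$isometric_strength) || mu$isometric_strength <= 0) {
      stop_gaitsens("gaitsens_invalid_model",
                    sprintf("muscle %s: isometric strength must be > 0", mu$name))
    }
    if (length(mu$moment_arms) < 1 || any(abs(mu$moment_arms) > 0.15)) {
      stop_gaitsens("gaitsens_invalid_model",
                    sprintf("muscle %s: needs >= 1 arm, all |arm| <= 0.15 m", mu$name))
    }
    if (!all(names(mu$moment_arms) %in% JOINT_DOFS)) {
      stop_gaitsens("gaitsens_invalid_model",
                    sprintf("muscle %s: unknown joint DoF in moment arms", mu$name))
    }
  }
  A <- moment_arm_matrix(model)
  for (d in JOINT_DOFS) {
    if (!any(A[d, ] > 0) || !any(A[d, ] < 0)) {
      stop_gaitsens("gaitsens_invalid_model",
                    sprintf("joint DoF %s lacks bidirectional muscle actuation", d))
    }
  }
  invisible(model)
}

#' Moment-arm matrix of a model
#'
#' @param model an `msk_model`
#' @param angles optional named joint-angle vector (deg); with the model's
#'   cosine-modulation flag on, each arm is scaled by `cos(angle / 2)`
#' @return matrix (6 DoFs x n muscles) of signed arms, m
#' @export
moment_arm_matrix <- function(model, angles = NULL) {
  n_mus <- length(model$muscles)
  A <- matrix(0, length(JOINT_DOFS), n_mus,
              dimnames = list(JOINT_DOFS, vapply(model$muscles, `[[`, "", "name")))
  for (j in seq_len(n_mus)) {
    arms <- model$muscles[[j]]$moment_arms
    A[names(arms), j] <- arms
  }
  if (isTRUE(model$arm_cosine_modulation) && !is.null(angles)) {
    scale <- cos(pi / 180 * angles[JOINT_DOFS] / 2)
    A <- A * as.numeric(scale)
  }
  A
}

#' Scale the reference model to a participant
#'
#' Segment lengths follow the participant's segment lengths, segment masses
#' scale with body mass, and isometric strengths scale with lean mass to the
#' two-thirds power (cross-sectional-area scaling):
#' `N_i <- N_i * (lean_participant / lean_reference)^(2/3)`.
#'
#' @param ref a reference `msk_model`
#' @param participant a `participant`
#' @return a scaled `msk_model`
#' @export
scale_model <- function(ref, participant) {
  lean_p <- participant$mass * (1 - participant$fat_fraction)
  mass_ratio <- participant$mass / ref$mass
  strength_ratio <- (lean_p / ref$lean_mass)^(2 / 3)
  if (!is.finite(mass_ratio) || mass_ratio <= 0 || strength_ratio <= 0) {
    stop_gaitsens("gaitsens_invalid_model", "non-positive scaling factors")
  }
  model <- ref
  model$participant_id <- participant$id
  model$mass <- participant$mass
  model$height <- participant$height
  model$fat_fraction <- participant$fat_fraction
  model$lean_mass <- lean_p
  for (s in names(model$segments)) {
    model$segments[[s]]$mass <- ref$segments[[s]]$mass * mass_ratio
    model$segments[[s]]$length <- participant$segment_lengths[[s]]
  }
  model$muscles <- lapply(ref$muscles, function(mu) {
    mu$isometric_strength <- mu$isometric_strength * strength_ratio
    mu
  })
  validate_msk_model(model)
  model
}

#' Reduce the isometric strength of one muscle group
#'
#' Returns a copy of the model in which every unit of `group` has its
#' isometric strength multiplied by `1 - fraction`; all other units are
#' untouched and the input model is not modified.
#'
#' @param model an `msk_model`
#' @param group one of the eight functional muscle groups
#' @param fraction reduction fraction in `[0, 1)` (the study design uses 0.40)
#' @return a new `msk_model`
#' @export
reduce_strength <- function(model, group, fraction) {
  group <- match.arg(group, MUSCLE_GROUPS)
  if (!is.finite(fraction) || fraction < 0 || fraction >= 1) {
    stop_gaitsens("gaitsens_invalid_configuration",
                  "invalid-configuration: fraction must lie in [0, 1)")
  }
  model$muscles <- lapply(model$muscles, function(mu) {
    if (mu$group == group) mu$isometric_strength <- mu$isometric_strength * (1 - fraction)
    mu
  })
  model
}

#' Build the four strength conditions of the study design
#'
#' The reference model plus three copies with a uniform 40% isometric
#' strength reduction applied to, respectively, the knee extensors, the hip
#' abductors, and the ankle extensors.
#'
#' @param model an `msk_model`
#' @param fraction reduction fraction (default 0.40)
#' @return named list of four `msk_model`s:
#'   `reference`, `knee_extensor`, `hip_abductor`, `ankle_extensor`
#' @export
build_strength_conditions <- function(model, fraction = 0.40) {
  list(
    reference = model,
    knee_extensor = reduce_strength(model, "knee_extensor", fraction),
    hip_abductor = reduce_strength(model, "hip_abductor", fraction),
    ankle_extensor = reduce_strength(model, "ankle_extensor", fraction)
  )
}

#' Isometric strengths of a model as a named vector
#' @param model an `msk_model`
#' @return named numeric vector, N
#' @export
muscle_strengths <- function(model) {
  vapply(model$muscles, function(mu) mu$isometric_strength, 0,
         USE.NAMES = FALSE) |>
    stats::setNames(vapply(model$muscles, `[[`, "", "name"))
}

#' @export
print.msk_model <- function(x, ...) {
  cat(sprintf("<msk_model %s>  mass %.1f kg, lean %.1f kg, %d muscles, 6 joint DoFs\n",
              x$participant_id, x$mass, x$lean_mass, length(x$muscles)))
  invisible(x)
}

#' Serialize a musculoskeletal model to a structured config file
#'
#' Writes segments, anthropometry and the full muscle roster (groups,
#' isometric strengths, moment arms, knee-crossing flags) to YAML for
#' audit; [read_model_config()] reconstructs the model.
#'
#' @param model an `msk_model`
#' @param path output YAML path
#' @export
write_model_config <- function(model, path) {
  obj <- list(
    participant_id = model$participant_id, mass = model$mass,
    height = model$height, fat_fraction = model$fat_fraction,
    arm_cosine_modulation = model$arm_cosine_modulation,
    segments = model$segments,
    muscles = lapply(model$muscles, function(mu) {
      mu$moment_arms <- as.list(mu$moment_arms)
      mu
    })
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Read a musculoskeletal model written by [write_model_config()]
#' @param path YAML path
#' @return an `msk_model`
#' @export
read_model_config <- function(path) {
  obj <- yaml::read_yaml(path)
  muscles <- lapply(obj$muscles, function(mu) {
    mu$moment_arms <- unlist(mu$moment_arms)
    mu
  })
  model <- structure(
    list(participant_id = obj$participant_id, mass = obj$mass,
         height = obj$height, fat_fraction = obj$fat_fraction,
         lean_mass = obj$mass * (1 - obj$fat_fraction),
         segments = obj$segments, joint_dofs = JOINT_DOFS, muscles = muscles,
         arm_cosine_modulation = obj$arm_cosine_modulation),
    class = "msk_model"
  )
  validate_msk_model(model)
  model
}
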