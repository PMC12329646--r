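# Seeded synthetic stance-phase gait generator.
#
# The generator emulates the statistical structure of a four-style gait study
# (normal, toe-out, toe-in, wide stance; five trials each): style-specific
# self-selected speeds, style offsets on foot progression angle / step width,
# smooth joint-angle templates, a double-peaked vertical GRF scaled to body
# weight, and a heel-to-toe CoP path whose mediolateral lever produces a
# realistic double-humped frontal knee moment downstream.

#' Default gait-generator parameters
#'
#' Per-style speed means/SDs are the emulated study's self-selected walking
#' speeds. Style offsets (+/-10 deg foot progression for toe-out/toe-in,
#' +0.10 m step width for wide) and the waveform knot templates are
#' configuration values, not measured quantities.
#'
#' @return named list of generator parameters
#' @export
default_generator_params <- function() {
  list(
    n_phase = 101L,
    speeds = list( # m/s, mean and SD per style
      normal  = c(mean = 1.16, sd = 0.14),
      toe_out = c(mean = 1.05, sd = 0.11),
      toe_in  = c(mean = 1.04, sd = 0.12),
      wide    = c(mean = 1.09, sd = 0.13)
    ),
    fpa_base = 5,                  # deg, habitual slight toe-out
    fpa_offset = list(toe_out = c(mean = 10, sd = 3), toe_in = c(mean = -10, sd = 3)),
    fpa_trial_sd = 0.5,            # deg, within-style trial jitter
    step_width_base = 0.12,        # m
    step_width_offset_wide = c(mean = 0.10, sd = 0.03),
    step_width_trial_sd = 0.005,   # m
    # joint-angle templates: spline knots at 0, 25, 50, 75, 100 %% stance (deg)
    angle_knots = list(
      hip_flex  = c(30, 12, -5, -15, -5),
      hip_add   = c(2, 6, 5, 2, -2),
      hip_rot   = c(0, 2, 2, 1, 0),
      knee_flex = c(6, 18, 8, 12, 38),
      ankle_pf  = c(0, -5, -8, 5, 18),
      ankle_inv = c(2, 0, 1, 3, 5)
    ),
    grf_hump = 0.65,               # depth of the mid-stance GRF valley
    grf_mean_bw = 1.05,            # mean vertical load over stance / body weight
    grf_ap_amp = 0.12,             # braking/propulsion amplitude, x body weight
    grf_ml_amp = -0.05,            # mediolateral amplitude, x body weight (- = medial)
    cop_heel_offset = -0.04,       # m, CoP start relative to ankle
    cop_travel = 0.20,             # m, heel-to-toe CoP excursion
    # mediolateral lever of the CoP relative to the ankle: two Gaussian humps;
    # together with the medial GRF component this produces a double-humped
    # frontal knee moment downstream
    kam_lever = c(early = 0.018, late = 0.020),        # m
    kam_lever_fpa = c(early = 0.0004, late = -0.0005), # m per deg of FPA change
    kam_lever_width = -0.05,       # m lever change per m of extra step width
    stance_fraction = 0.62,        # stance / stride time
    stride_factor = 0.80,          # stride length = factor * height * sqrt(v/1.16)
    angle_noise = 1.0,             # deg, smooth trial-to-trial noise
    grf_noise = 0.015,             # x body weight
    cop_noise = 0.002              # m
  )
}

style_index <- function(style) match(style, GAIT_STYLES)

# Per-participant style offsets, deterministic in (participant seed, style).
# Offsets are truncated at +/-2 SD and trial jitter kept small so the style
# orderings (toe-out FPA > normal > toe-in; wide step width > normal) hold
# for every trial of a participant, as they did for the study's instructed
# gait modifications.
participant_style_offsets <- function(participant, style, gp) {
  pseed <- participant$seed
  if (is.na(pseed)) pseed <- sum(utf8ToInt(participant$id))
  fpa_off <- 0
  sw_off <- 0
  if (style %in% c("toe_out", "toe_in")) {
    set.seed(child_seed(pseed, 7000 + style_index(style)))
    o <- gp$fpa_offset[[style]]
    fpa_off <- rtruncnorm3(1, o["mean"], o["sd"], n_sd = 2)
  }
  if (style == "wide") {
    set.seed(child_seed(pseed, 7000 + style_index(style)))
    o <- gp$step_width_offset_wide
    sw_off <- rtruncnorm3(1, o["mean"], o["sd"], n_sd = 2)
  }
  list(fpa = fpa_off, step_width = sw_off)
}

#' Generate one synthetic stance-phase gait trial
#'
#' Speed is drawn from the style's truncated normal; joint angles follow
#' smooth spline templates; the vertical GRF is a double-peaked waveform
#' scaled so the mean vertical load over stance is near body weight; style
#' offsets are applied to foot progression angle (toe-out/toe-in), step width
#' and the frontal CoP lever (wide); smooth low-amplitude noise makes
#' repeated trials differ.
#'
#' @param participant a `participant`
#' @param style one of `"normal"`, `"toe_out"`, `"toe_in"`, `"wide"`
#' @param trial_index integer trial number
#' @param gen_params generator configuration, see [default_generator_params()]
#' @param seed integer seed for this trial
#' @return a [gait_trial()]
#' @export
generate_trial <- function(participant, style, trial_index = 1L,
                           gen_params = default_generator_params(), seed = 1L) {
  if (!style %in% GAIT_STYLES) {
    stop_gaitsens("gaitsens_invalid_configuration",
                  sprintf("invalid-configuration: unknown gait style '%s'", style))
  }
  gp <- gen_params
  n <- gp$n_phase
  t <- seq(0, 1, length.out = n)
  off <- participant_style_offsets(participant, style, gp)

  set.seed(as.integer(seed))
  sp <- gp$speeds[[style]]
  speed <- rtruncnorm3(1, sp["mean"], sp["sd"])
  fpa <- gp$fpa_base + off$fpa + stats::rnorm(1, 0, gp$fpa_trial_sd)
  step_width <- gp$step_width_base + off$step_width + stats::rnorm(1, 0, gp$step_width_trial_sd)

  stride_length <- gp$stride_factor * participant$height * sqrt(speed / 1.16)
  stance_time <- gp$stance_fraction * stride_length / speed

  # joint angles: natural spline through the template knots + smooth noise
  tk <- seq(0, 1, length.out = 5)
  ang <- sapply(ANGLE_COLS, function(a) {
    base <- stats::spline(tk, gp$angle_knots[[a]], xout = t, method = "natural")$y
    base + smooth_noise(t, gp$angle_noise)
  })
  if (style == "wide") ang[, "hip_add"] <- ang[, "hip_add"] - 4  # abducted limb
  ang[, "knee_flex"] <- pmin(pmax(ang[, "knee_flex"], 0), 90)

  bw <- participant$mass * 9.81
  b <- min(max(gp$grf_hump * sqrt(speed / 1.16), 0.3), 0.8)
  amp <- gp$grf_mean_bw / (2 / pi - 2 * b / (3 * pi))
  fy <- bw * pmax(sin(pi * t) * (amp * (1 + b * cos(2 * pi * t))) +
                    smooth_noise(t, gp$grf_noise * amp), 0)
  fy[c(1, n)] <- 0
  fx <- bw * (-gp$grf_ap_amp * (speed / 1.16) * sin(2 * pi * t) +
                smooth_noise(t, gp$grf_noise))
  fz <- bw * (gp$grf_ml_amp * sin(pi * t) + smooth_noise(t, gp$grf_noise / 2))

  ankle_z <- step_width / 2
  cop_x <- gp$cop_heel_offset + gp$cop_travel * smoothstep(t) + smooth_noise(t, gp$cop_noise)
  dfpa <- fpa - gp$fpa_base
  dwidth <- step_width - gp$step_width_base
  lever_early <- gp$kam_lever["early"] + gp$kam_lever_fpa["early"] * dfpa +
    gp$kam_lever_width * dwidth
  lever_late <- gp$kam_lever["late"] + gp$kam_lever_fpa["late"] * dfpa +
    gp$kam_lever_width * dwidth
  lever <- lever_early * exp(-((t - 0.25) / 0.16)^2) +
    lever_late * exp(-((t - 0.78) / 0.14)^2)
  cop_z <- ankle_z - lever + smooth_noise(t, gp$cop_noise)

  gait_trial(
    participant_id = participant$id, style = style,
    phase_grid = 100 * t,
    joint_angles = ang,
    grf = cbind(grf_x = fx, grf_y = fy, grf_z = fz),
    cop = cbind(cop_x = cop_x, cop_z = cop_z),
    foot_progression_angle = fpa, step_width = step_width,
    speed = speed, stance_time = stance_time,
    trial_index = trial_index, seed = as.integer(seed)
  )
}

#' Generate a full synthetic cohort of gait trials
#'
#' Hierarchical seeding: participant `i` uses seed `seed + i`, and every
#' (participant, style, trial) cell derives its own child seed, so any subset
#' is independently reproducible.
#'
#' @param n_participants number of participants (study design: 7)
#' @param n_trials trials per participant and style (study design: 5)
#' @param styles character vector of gait styles
#' @param seed master seed
#' @param cohort_params see [default_cohort_params()]
#' @param gen_params see [default_generator_params()]
#' @return object of class `gait_cohort`: list with `participants` and
#'   `trials` (list of [gait_trial()])
#' @export
generate_cohort <- function(n_participants = 7L, n_trials = 5L,
                            styles = GAIT_STYLES, seed = 0L,
                            cohort_params = default_cohort_params(),
                            gen_params = default_generator_params()) {
  stopifnot(n_participants >= 1, n_trials >= 1)
  participants <- lapply(seq_len(n_participants), function(i) {
    sample_participant(cohort_params, seed = as.integer(seed) + i)
  })
  trials <- list()
  for (p in participants) {
    for (s in styles) {
      for (k in seq_len(n_trials)) {
        tseed <- child_seed(p$seed, 1000 * style_index(s) + k)
        trials[[length(trials) + 1L]] <-
          generate_trial(p, s, trial_index = k, gen_params = gen_params, seed = tseed)
      }
    }
  }
  structure(list(participants = participants, trials = trials,
                 master_seed = as.integer(seed)),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort>  %d participants, %d trials (master seed %d)\n",
              length(x$participants), length(x$trials), x$master_seed))
  invisible(x)
}
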