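# Synthetic cohort: participant anthropometrics.

#' Default cohort distribution parameters
#'
#' Mean/SD of body mass and height for the emulated cohort of healthy adult
#' males (76.3 +/- 8.6 kg, 1.777 +/- 0.037 m), plus the age used by the
#' body-fat regression and the segment-length fractions of height.
#'
#' @return named list of cohort parameters
#' @export
default_cohort_params <- function() {
  list(
    mass_mean = 76.3, mass_sd = 8.6,        # kg
    height_mean = 1.777, height_sd = 0.037, # m
    age = 29,                               # years, cohort mean
    sex = "male",
    # segment lengths as fractions of stature (standard anthropometric tables)
    segment_fractions = c(thigh = 0.245, shank = 0.246, foot = 0.152),
    # adult BMI -> body-fat%% linear regression, percent scale:
    # fat%% = a * bmi + c_age * age + male_offset
    fat_a = 1.20, fat_c_age = 0.23, fat_male_offset = -16.2
  )
}

#' Estimate body-fat fraction from body mass index
#'
#' Linear adult regression of body-fat percent on BMI and age with a male
#' offset, converted to a fraction and clamped to the physiologically
#' plausible band (0.03, 0.6). Coefficients are configuration values.
#'
#' @param bmi body mass index, kg/m^2; must lie in [10, 60]
#' @param params cohort parameter list (see [default_cohort_params()])
#' @return body-fat fraction, dimensionless
#' @examples
#' estimate_fat_fraction(24.2)
#' @export
estimate_fat_fraction <- function(bmi, params = default_cohort_params()) {
  if (any(!is.finite(bmi)) || any(bmi < 10) || any(bmi > 60)) {
    stop_gaitsens("gaitsens_out_of_range", "bmi outside [10, 60]")
  }
  pct <- params$fat_a * bmi + params$fat_c_age * params$age + params$fat_male_offset
  pmin(pmax(pct / 100, 0.03), 0.6)
}

#' Sample a synthetic participant
#'
#' Mass and height are drawn from normal distributions truncated at
#' +/- 3 SD; fat fraction follows from BMI via [estimate_fat_fraction()];
#' segment lengths are fixed fractions of height.
#'
#' @param cohort_params distribution spec, see [default_cohort_params()]
#' @param seed nonnegative integer seed
#' @param id participant label
#' @return object of class `participant`
#' @export
sample_participant <- function(cohort_params = default_cohort_params(), seed = 1L,
                               id = sprintf("P%03d", seed)) {
  p <- cohort_params
  for (nm in c("mass_mean", "mass_sd", "height_mean", "height_sd")) {
    if (!is.finite(p[[nm]])) {
      stop_gaitsens("gaitsens_invalid_configuration",
                    sprintf("invalid-configuration: %s is not finite", nm))
    }
  }
  if (p$mass_mean <= 0 || p$height_mean <= 0 || p$mass_sd < 0 || p$height_sd < 0) {
    stop_gaitsens("gaitsens_invalid_configuration",
                  "invalid-configuration: non-positive mean or negative SD")
  }
  set.seed(as.integer(seed))
  mass <- rtruncnorm3(1, p$mass_mean, p$mass_sd)
  height <- rtruncnorm3(1, p$height_mean, p$height_sd)
  bmi <- mass / height^2
  participant(
    id = id, mass = mass, height = height,
    fat_fraction = estimate_fat_fraction(bmi, p),
    segment_lengths = p$segment_fractions * height,
    seed = as.integer(seed)
  )
}

#' Construct and validate a participant
#'
#' @param id label
#' @param mass body mass, kg
#' @param height stature, m
#' @param fat_fraction body-fat fraction in (0.03, 0.6)
#' @param segment_lengths named numeric (thigh, shank, foot), m
#' @param seed integer seed used to draw the participant (optional)
#' @return object of class `participant`
#' @export
participant <- function(id, mass, height, fat_fraction, segment_lengths, seed = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1)
  if (!is.finite(mass) || mass <= 0) stop_gaitsens("gaitsens_invalid_configuration", "mass must be > 0")
  if (!is.finite(height) || height <= 0) stop_gaitsens("gaitsens_invalid_configuration", "height must be > 0")
  if (!(fat_fraction > 0.03 - 1e-12 && fat_fraction < 0.6 + 1e-12)) {
    stop_gaitsens("gaitsens_invalid_configuration", "fat_fraction outside (0.03, 0.6)")
  }
  if (any(segment_lengths <= 0) || sum(segment_lengths) >= height) {
    stop_gaitsens("gaitsens_invalid_configuration",
                  "segment lengths must be positive and sum to less than height")
  }
  structure(
    list(id = id, mass = mass, height = height, bmi = mass / height^2,
         fat_fraction = fat_fraction, segment_lengths = segment_lengths,
         seed = seed),
    class = "participant"
  )
}

#' @export
print.participant <- function(x, ...) {
  cat(sprintf("<participant %s>  mass %.1f kg, height %.3f m, BMI %.1f, fat %.1f%%\n",
              x$id, x$mass, x$height, x$bmi, 100 * x$fat_fraction))
  invisible(x)
}
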