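# Synthetic cohort and gait-trial generator.

test_that("participant sampling respects the cohort distribution contract", {
  # truncation at +/- 3 SD of the cohort mass distribution
  for (seed in 1:50) {
    p <- sample_participant(seed = seed)
    expect_gte(p$mass, 76.3 - 3 * 8.6)
    expect_lte(p$mass, 76.3 + 3 * 8.6)
    expect_gte(p$height, 1.777 - 3 * 0.037)
    expect_lte(p$height, 1.777 + 3 * 0.037)
    expect_true(p$fat_fraction > 0.03 && p$fat_fraction < 0.6)
    expect_lt(sum(p$segment_lengths), p$height)
  }
  # degenerate distribution
  cp <- default_cohort_params()
  cp$mass_sd <- 0; cp$height_sd <- 0
  p0 <- sample_participant(cp, seed = 3)
  expect_identical(p0$mass, 76.3)
  expect_identical(p0$height, 1.777)
  # seeded determinism
  expect_identical(sample_participant(seed = 11), sample_participant(seed = 11))
  # invalid configuration
  cp$mass_mean <- -1
  expect_error(sample_participant(cp, seed = 1), class = "gaitsens_invalid_configuration")
  cp$mass_mean <- NaN
  expect_error(sample_participant(cp, seed = 1), class = "gaitsens_invalid_configuration")
})

test_that("fat fraction estimate is monotone, matches the configured regression, and clamps", {
  expect_gt(estimate_fat_fraction(30), estimate_fat_fraction(20))
  # direct evaluation of the configured linear form:
  # (1.20 * 20 + 0.23 * 29 - 16.2) / 100 = 0.1447
  expect_equal(estimate_fat_fraction(20), 0.1447, tolerance = 1e-12)
  # clamp floor for coefficients that produce a negative percent
  cp <- default_cohort_params()
  cp$fat_male_offset <- -60
  expect_equal(estimate_fat_fraction(12, cp), 0.03)
  expect_error(estimate_fat_fraction(9), class = "gaitsens_out_of_range")
  expect_error(estimate_fat_fraction(61), class = "gaitsens_out_of_range")
})

test_that("generated trials satisfy all trial invariants over many seeds", {
  p <- sample_participant(seed = 1)
  for (seed in 1:250) {
    style <- c("normal", "toe_out", "toe_in", "wide")[1 + seed %% 4]
    tr <- generate_trial(p, style, seed = seed)
    expect_silent(validate_gait_trial(tr)) # grid, GRF >= 0, knee range, endpoints
  }
})

test_that("speed draws stay inside +/- 3 SD of the style mean", {
  p <- sample_participant(seed = 2)
  sp <- sapply(1:100, function(s) generate_trial(p, "normal", seed = s)$speed)
  expect_true(all(sp >= 1.16 - 3 * 0.14 & sp <= 1.16 + 3 * 0.14))
})

test_that("zero waveform noise makes trials identical except the speed-dependent parts", {
  p <- sample_participant(seed = 1)
  gp <- default_generator_params()
  gp$angle_noise <- 0; gp$grf_noise <- 0; gp$cop_noise <- 0
  gp$fpa_trial_sd <- 0; gp$step_width_trial_sd <- 0
  t1 <- generate_trial(p, "normal", trial_index = 1, gen_params = gp, seed = 21)
  t2 <- generate_trial(p, "normal", trial_index = 2, gen_params = gp, seed = 22)
  expect_false(t1$speed == t2$speed)
  expect_equal(t1$joint_angles, t2$joint_angles, tolerance = 1e-12)
  expect_equal(t1$foot_progression_angle, t2$foot_progression_angle, tolerance = 1e-12)
})

test_that("mean vertical load over stance is near body weight (quadrature oracle)", {
  p <- sample_participant(seed = 4)
  for (seed in 1:10) {
    tr <- generate_trial(p, "normal", seed = seed)
    dt <- tr$stance_time / (length(tr$phase_grid) - 1)
    fy <- tr$grf[, "grf_y"]
    integral <- dt * (sum(fy) - (fy[1] + fy[length(fy)]) / 2) # trapezoid
    ratio <- integral / tr$stance_time / (p$mass * 9.81)
    expect_gte(ratio, 0.9)
    expect_lte(ratio, 1.2)
  }
})

test_that("vertical GRF is double-peaked with a mid-stance valley", {
  p <- sample_participant(seed = 5)
  gp <- default_generator_params()
  gp$grf_noise <- 0
  tr <- generate_trial(p, "normal", gen_params = gp, seed = 9)
  fy <- tr$grf[, "grf_y"]
  n <- length(fy)
  interior <- 2:(n - 1)
  loc_max <- interior[fy[interior] > fy[interior - 1] & fy[interior] > fy[interior + 1]]
  loc_min <- interior[fy[interior] < fy[interior - 1] & fy[interior] < fy[interior + 1]]
  expect_identical(length(loc_max), 2L)
  expect_identical(length(loc_min), 1L)
  expect_true(loc_min > min(loc_max) && loc_min < max(loc_max))
})

test_that("style offsets order every trial of a participant", {
  p <- sample_participant(seed = 6)
  nrm <- lapply(1:5, function(k) generate_trial(p, "normal", k, seed = 100 + k))
  out <- lapply(1:5, function(k) generate_trial(p, "toe_out", k, seed = 200 + k))
  tin <- lapply(1:5, function(k) generate_trial(p, "toe_in", k, seed = 300 + k))
  wid <- lapply(1:5, function(k) generate_trial(p, "wide", k, seed = 400 + k))
  fpa <- function(l) sapply(l, `[[`, "foot_progression_angle")
  sw <- function(l) sapply(l, `[[`, "step_width")
  expect_true(min(fpa(out)) > max(fpa(nrm)))
  expect_true(max(fpa(tin)) < min(fpa(nrm)))
  expect_true(min(sw(wid)) > max(sw(nrm)))
})

test_that("normal gait is faster on average than toe-in and toe-out", {
  p <- sample_participant(seed = 7)
  mean_speed <- function(style) {
    mean(sapply(1:100, function(s) generate_trial(p, style, seed = s)$speed))
  }
  m_n <- mean_speed("normal")
  expect_gt(m_n, mean_speed("toe_in"))
  expect_gt(m_n, mean_speed("toe_out"))
})

test_that("cohort generation has the study design shape and hierarchical reproducibility", {
  co <- generate_cohort(7, 5, seed = 0)
  expect_length(co$trials, 7 * 4 * 5)
  keys <- sapply(co$trials, function(tr) paste(tr$participant_id, tr$style, tr$trial_index))
  expect_identical(anyDuplicated(keys), 0L)
  # regeneration is byte-identical through serialization
  co2 <- generate_cohort(7, 5, seed = 0)
  d <- tempfile(); dir.create(d)
  write_gait_trial(co$trials[[17]], file.path(d, "a.csv"))
  write_gait_trial(co2$trials[[17]], file.path(d, "b.csv"))
  expect_identical(unname(tools::md5sum(file.path(d, "a.csv"))),
                   unname(tools::md5sum(file.path(d, "b.csv"))))
  # any subset regenerates independently: same trial from generate_trial alone
  tr <- co$trials[[17]]
  p <- Find(function(x) x$id == tr$participant_id, co$participants)
  again <- generate_trial(p, tr$style, tr$trial_index, seed = tr$seed)
  expect_equal(again$grf, tr$grf, tolerance = 0)
  unlink(d, recursive = TRUE)
})

test_that("trial CSV serialization round-trips to 1e-12", {
  p <- sample_participant(seed = 8)
  tr <- generate_trial(p, "wide", seed = 77)
  f <- tempfile(fileext = ".csv")
  write_gait_trial(tr, f)
  back <- read_gait_trial(f)
  expect_equal(back$joint_angles, tr$joint_angles, tolerance = 1e-12)
  expect_equal(back$grf, tr$grf, tolerance = 1e-12)
  expect_equal(back$cop, tr$cop, tolerance = 1e-12)
  expect_equal(back$speed, tr$speed, tolerance = 1e-12)
  expect_equal(back$step_width, tr$step_width, tolerance = 1e-12)
  unlink(c(f, paste0(f, ".meta.yaml")))
})

test_that("unknown styles are rejected", {
  p <- sample_participant(seed = 9)
  expect_error(generate_trial(p, "skipping", seed = 1),
               class = "gaitsens_invalid_configuration")
})
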