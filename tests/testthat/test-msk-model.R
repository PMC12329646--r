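# Musculoskeletal model scaling and strength conditions.

test_that("scaling a participant identical to the reference is the identity", {
  ref <- reference_model()
  p <- participant("same", mass = ref$mass, height = ref$height,
                   fat_fraction = ref$fat_fraction,
                   segment_lengths = c(thigh = 0.245, shank = 0.246, foot = 0.152) * ref$height)
  scaled <- scale_model(ref, p)
  expect_equal(muscle_strengths(scaled), muscle_strengths(ref), tolerance = 1e-12)
  expect_equal(scaled$segments$thigh$mass, ref$segments$thigh$mass, tolerance = 1e-12)
})

test_that("strength follows lean mass to the two-thirds power", {
  ref <- reference_model(mass = 75, fat_fraction = 0.20) # lean 60 kg
  # lean mass ratio 8 -> strengths x4
  p8 <- participant("x8", mass = 8 * 60 / (1 - 0.2), height = 1.75,
                    fat_fraction = 0.20,
                    segment_lengths = c(thigh = 0.42, shank = 0.43, foot = 0.26))
  expect_equal(muscle_strengths(scale_model(ref, p8)),
               4 * muscle_strengths(ref), tolerance = 1e-12)
  # cohort-mean participant: factor computed from the scaling formula
  h <- 1.777; mass <- 76.3
  ff <- estimate_fat_fraction(mass / h^2) # 0.1947 at the cohort-mean BMI
  pc <- participant("cohort", mass, h, ff,
                    segment_lengths = c(thigh = 0.245, shank = 0.246, foot = 0.152) * h)
  factor <- (mass * (1 - ff) / 60)^(2 / 3)
  expect_equal(muscle_strengths(scale_model(ref, pc)),
               factor * muscle_strengths(ref), tolerance = 1e-12)
  # homogeneity: lean mass x c -> strengths x c^(2/3), with c from mass only
  c_ratio <- 1.3
  p2 <- participant("hom", mass = 75 * c_ratio, height = 1.75, fat_fraction = 0.20,
                    segment_lengths = c(thigh = 0.42, shank = 0.43, foot = 0.26))
  expect_equal(muscle_strengths(scale_model(ref, p2)),
               c_ratio^(2 / 3) * muscle_strengths(ref), tolerance = 1e-12)
})

test_that("group strength reduction is isolated, copy-on-write, and bounded", {
  m <- reference_model()
  red <- reduce_strength(m, "ankle_extensor", 0.40)
  s0 <- muscle_strengths(m); s1 <- muscle_strengths(red)
  # uniform 40% cut on the triceps surae only
  expect_equal(s1[["soleus"]], 0.6 * s0[["soleus"]], tolerance = 1e-12)
  expect_equal(s1[["gastrocnemius"]], 0.6 * s0[["gastrocnemius"]], tolerance = 1e-12)
  others <- setdiff(names(s0), c("soleus", "gastrocnemius"))
  expect_identical(s1[others], s0[others])
  # soleus at 3500 N drops to 2100 N
  expect_equal(s1[["soleus"]], 2100)
  # input untouched; fraction 0 is the identity
  expect_identical(muscle_strengths(m), s0)
  expect_identical(muscle_strengths(reduce_strength(m, "knee_extensor", 0)), s0)
  # knee-extensor reduction leaves the abductors alone
  redk <- reduce_strength(m, "knee_extensor", 0.40)
  expect_identical(muscle_strengths(redk)[["gluteus_medius"]], s0[["gluteus_medius"]])
  expect_error(reduce_strength(m, "knee_extensor", 1),
               class = "gaitsens_invalid_configuration")
  expect_error(reduce_strength(m, "knee_extensor", -0.1),
               class = "gaitsens_invalid_configuration")
})

test_that("the four strength conditions match the study design", {
  m <- reference_model()
  conds <- build_strength_conditions(m)
  expect_named(conds, c("reference", "knee_extensor", "hip_abductor", "ankle_extensor"))
  expect_identical(muscle_strengths(conds$reference), muscle_strengths(m))
  for (g in c("knee_extensor", "hip_abductor", "ankle_extensor")) {
    s <- muscle_strengths(conds[[g]]); s0 <- muscle_strengths(m)
    grp <- vapply(m$muscles, function(mu) mu$group == g, TRUE)
    nm <- vapply(m$muscles, `[[`, "", "name")
    expect_equal(s[nm[grp]], 0.6 * s0[nm[grp]], tolerance = 1e-12)
    expect_identical(s[nm[!grp]], s0[nm[!grp]])
  }
})

test_that("bidirectional actuation survives repeated strength reductions", {
  m <- reference_model()
  for (g in c("ankle_extensor", "hip_abductor", "knee_extensor", "hip_flexor")) {
    m <- reduce_strength(m, g, 0.40)
  }
  expect_silent(validate_msk_model(m))
  A <- moment_arm_matrix(m)
  for (d in rownames(A)) {
    expect_true(any(A[d, ] > 0) && any(A[d, ] < 0))
  }
})

test_that("model validation rejects non-physical rosters", {
  m <- reference_model()
  m$muscles[[1]]$isometric_strength <- -5
  expect_error(validate_msk_model(m), class = "gaitsens_invalid_model")
  m <- reference_model()
  m$muscles[[1]]$moment_arms <- c(knee_flex = 0.3)
  expect_error(validate_msk_model(m), class = "gaitsens_invalid_model")
})

test_that("models round-trip through their YAML audit format", {
  p <- sample_participant(seed = 4)
  m <- scale_model(reference_model(), p)
  f <- tempfile(fileext = ".yaml")
  write_model_config(m, f)
  back <- read_model_config(f)
  expect_equal(muscle_strengths(back), muscle_strengths(m), tolerance = 1e-15)
  expect_equal(moment_arm_matrix(back), moment_arm_matrix(m), tolerance = 1e-15)
  expect_equal(back$segments, m$segments, tolerance = 1e-15)
  unlink(f)
})
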