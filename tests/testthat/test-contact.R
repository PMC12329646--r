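# Elastic-foundation tibiofemoral contact and stress summaries.

test_that("pure axial load on symmetric geometry gives mirror-identical compartments", {
  geom <- plateau_geometry()
  tr <- make_load_trace(axial = c(0, 2000, 1000), meta = list())
  sf <- solve_contact(tr, geom)
  expect_lt(max(abs(sf$stress$medial - sf$stress$lateral)), 1e-9)
  # integrated pressure equals the applied load within 0.1%
  total <- compartment_load(sf, geom, "medial", 2) +
    compartment_load(sf, geom, "lateral", 2)
  expect_lt(abs(total - 2000) / 2000, 1e-3)
})

test_that("every solved sample balances the applied loads within 0.1%", {
  geom <- plateau_geometry()
  tr <- make_load_trace(axial = seq(0, 2500, length.out = 11),
                        adduction = seq(0, 30, length.out = 11),
                        fx = seq(0, 120, length.out = 11),
                        fz = seq(0, 60, length.out = 11))
  sf <- solve_contact(tr, geom)
  expect_true(all(sf$residual <= 1e-3))
})

test_that("zero load yields a zero field and pose", {
  geom <- plateau_geometry()
  tr <- make_load_trace(axial = c(0, 0, 0))
  sf <- solve_contact(tr, geom)
  expect_identical(max(sf$stress$medial), 0)
  expect_identical(max(abs(sf$pose[, 1:4])), 0)
})

test_that("the stiff-foundation compartment split approaches F/2 +/- M/d", {
  geom <- plateau_geometry(modulus = 2000e6)
  F <- 1000; M <- 10; d <- 0.040
  tr <- make_load_trace(axial = c(0, F, F), adduction = c(0, M, M))
  sf <- solve_contact(tr, geom)
  med <- compartment_load(sf, geom, "medial", 2)
  lat <- compartment_load(sf, geom, "lateral", 2)
  expect_lt(abs(med - (F / 2 + M / d)) / (F / 2 + M / d), 0.05)
  expect_lt(abs(lat - (F / 2 - M / d)) / (F / 2 - M / d), 0.05)
})

test_that("medial load share is non-decreasing over a 21-point adduction-moment sweep", {
  geom <- plateau_geometry()
  shares <- sapply(seq(-10, 30, length.out = 21), function(M) {
    sf <- solve_contact(make_load_trace(axial = c(0, 2000, 2000),
                                        adduction = c(0, M, M)), geom)
    med <- compartment_load(sf, geom, "medial", 2)
    lat <- compartment_load(sf, geom, "lateral", 2)
    med / (med + lat)
  })
  expect_true(all(diff(shares) >= -1e-12))
})

test_that("upper-quartile summary is stable under mesh refinement", {
  tr <- make_load_trace(axial = c(0, 2000, 1200), adduction = c(0, 12, 8))
  u1 <- upper_quartile_summary(solve_contact(tr, plateau_geometry(nx = 8, nz = 8)))
  u2 <- upper_quartile_summary(solve_contact(tr, plateau_geometry(nx = 16, nz = 16)))
  for (cn in c("medial", "lateral")) {
    expect_lt(abs(u1[[cn]][2] - u2[[cn]][2]) / u2[[cn]][2], 0.02)
  }
})

test_that("removing the connectors never decreases the AP translation magnitude", {
  geom <- plateau_geometry()
  tr <- make_load_trace(axial = c(0, 2000, 1500), fx = c(0, 80, 60))
  with_c <- solve_contact(tr, geom, connector_set())
  no_c <- solve_contact(tr, geom, connector_set(0, 0, 0, 0))
  expect_true(all(abs(no_c$pose[, "ap_trans"]) >= abs(with_c$pose[, "ap_trans"]) - 1e-15))
})

test_that("connector defaults serialize exactly as the restraint stiffnesses", {
  cs <- connector_set()
  expect_identical(cs$tf_translation_stiffness, 0.5)   # N/mm
  expect_identical(cs$tf_rotation_stiffness, 1.2)      # Nm/deg
  expect_identical(cs$patellar_translation_stiffness, 0.2)
  expect_identical(cs$patellar_rotation_stiffness, 0.9)
  expect_error(connector_set(-1), class = "gaitsens_invalid_configuration")
})

test_that("upper-quartile summary equals a direct ranking oracle", {
  mk_field <- function(stress_med, stress_lat) {
    structure(list(phase_grid = seq(0, 100, length.out = nrow(stress_med)),
                   stress = list(medial = stress_med, lateral = stress_lat),
                   mask = list(medial = stress_med > 0, lateral = stress_lat > 0),
                   pose = NULL, residual = 0, meta = list()),
              class = "stress_field")
  }
  oracle <- function(row) {
    contact <- row[row > 0]
    if (!length(contact)) return(0)
    k <- ceiling(0.25 * length(contact))
    mean(sort(contact, decreasing = TRUE)[seq_len(k)])
  }
  set.seed(12)
  for (rep in 1:200) {
    s <- matrix(pmax(stats::rnorm(2 * 16, 1, 2), 0), 2, 16)
    l <- matrix(pmax(stats::rnorm(2 * 16, 1, 2), 0), 2, 16)
    u <- upper_quartile_summary(mk_field(s, l))
    expect_equal(u$medial, apply(s, 1, oracle), tolerance = 1e-12)
    expect_equal(u$lateral, apply(l, 1, oracle), tolerance = 1e-12)
  }
  # uniform stress over the contact area returns that stress
  su <- matrix(c(rep(2.5, 10), rep(0, 6)), 1, 16)
  expect_equal(upper_quartile_summary(mk_field(su, su))$medial, 2.5)
  # 8 contacting elements 1..8: mean of the top two is 7.5
  s8 <- matrix(c(1:8, rep(0, 8)), 1, 16)
  expect_equal(upper_quartile_summary(mk_field(s8, s8))$medial, 7.5)
  # zero-pressure elements are excluded from the quartile base
  s_half <- matrix(c(4, 4, rep(0, 14)), 1, 16) # 2 contacting -> top 1 -> 4
  expect_equal(upper_quartile_summary(mk_field(s_half, s_half))$medial, 4)
  # empty contact flags the sample
  s0 <- matrix(0, 1, 16)
  u0 <- upper_quartile_summary(mk_field(s0, s0))
  expect_identical(u0$medial, 0)
  expect_true(u0$no_contact$medial[1])
})
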