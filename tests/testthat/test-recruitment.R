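# Cubic-criterion static optimization.

test_that("forced single-muscle solution is exact", {
  pr <- recruitment_problem(matrix(1, 1, 1), r = 100, N = 1000)
  s <- solve_recruitment(pr)
  expect_equal(s$f, 100, tolerance = 1e-10)
  expect_equal(s$activations, 0.1, tolerance = 1e-10)
  expect_equal(s$objective, 0.001, tolerance = 1e-10)
})

test_that("two parallel muscles split as N^(3/2) (Lagrange closed form)", {
  pr <- recruitment_problem(matrix(c(1, 1), 1, 2), r = 300, N = c(1000, 500))
  s <- solve_recruitment(pr)
  f1 <- 300 * 1000^1.5 / (1000^1.5 + 500^1.5)
  expect_equal(s$f, c(f1, 300 - f1), tolerance = 1e-8)
  expect_lt(s$kkt_residual, 1e-8)
})

test_that("zero demand yields zero force and zero criterion", {
  pr <- recruitment_problem(matrix(c(1, -1, 2, 0.5), 2, 2), r = c(0, 0),
                            N = c(800, 900))
  s <- solve_recruitment(pr)
  expect_identical(s$f, c(0, 0))
  expect_identical(s$objective, 0)
})

test_that("solver matches the grid-search oracle on random small problems", {
  set.seed(101)
  done <- 0
  while (done < 25) {
    prob <- random_small_problem()
    s <- tryCatch(solve_recruitment(recruitment_problem(prob$C, prob$r, prob$N)),
                  gaitsens_error = function(e) NULL)
    if (is.null(s)) next # infeasible draw
    f_oracle <- grid_search_recruitment(prob$C, prob$r, prob$N)
    expect_lt(max(abs(s$f - f_oracle)), 0.2)
    done <- done + 1
  }
})

test_that("KKT certificates hold on random feasible problems", {
  set.seed(7)
  for (k in 1:200) {
    n <- sample(3:17, 1); m <- sample(1:6, 1)
    C <- matrix(stats::rnorm(m * n), m, n)
    if (qr(C)$rank < m) next
    N <- runif(n, 100, 3000)
    r <- stats::rnorm(m, 0, 50)
    s <- tryCatch(solve_recruitment(recruitment_problem(C, r, N)),
                  gaitsens_error = function(e) NULL)
    if (is.null(s)) next
    expect_lt(s$kkt_residual, 1e-6)
  }
})

test_that("weakening one of two parallel muscles shifts force to the other", {
  N <- c(1000, 500)
  base <- solve_recruitment(recruitment_problem(matrix(c(1, 1), 1, 2), 300, N))
  weak <- solve_recruitment(recruitment_problem(matrix(c(1, 1), 1, 2), 300,
                                                c(0.6 * N[1], N[2])))
  expect_lt(weak$f[1], base$f[1])
  expect_gt(weak$f[2], base$f[2])
  expect_equal(sum(weak$f), 300, tolerance = 1e-9)
})

test_that("rectus femoris does not lose activation when hip abductors weaken", {
  p <- sample_participant(seed = 1)
  m <- scale_model(reference_model(), p)
  tr <- generate_trial(p, "normal", seed = 7)
  ld <- inverse_dynamics(tr, m)
  weak <- reduce_strength(m, "hip_abductor", 0.40)
  i <- 81 # late stance, hip flexion demand active
  a_ref <- solve_recruitment(assemble_problem(ld, m, i))$activations
  a_weak <- solve_recruitment(assemble_problem(ld, weak, i))$activations
  rf <- which(vapply(m$muscles, `[[`, "", "name") == "rectus_femoris")
  expect_gte(a_weak[rf], a_ref[rf])
})

test_that("solutions are homogeneous in the demand and invariant to uniform strength scaling", {
  set.seed(33)
  C <- matrix(stats::rnorm(4 * 10), 4, 10)
  N <- runif(10, 500, 3000)
  # guarantee feasibility: a demand produced by a nonnegative recruitment
  r <- as.numeric((C * rep(N, each = 4)) %*% runif(10, 0, 0.2))
  s1 <- solve_recruitment(recruitment_problem(C, r, N))
  s2 <- solve_recruitment(recruitment_problem(C, 2 * r, N))
  expect_equal(s2$f, 2 * s1$f, tolerance = 1e-6 * (1 + max(abs(s1$f))))
  s3 <- solve_recruitment(recruitment_problem(C, r, 3 * N))
  expect_equal(s3$f, s1$f, tolerance = 1e-6 * (1 + max(abs(s1$f))))
})

test_that("order-generic criterion approaches min-max recruitment as p grows", {
  # two parallel muscles with equal strengths: any p splits evenly; with
  # unequal strengths, p -> infinity equalizes activations
  pr <- recruitment_problem(matrix(c(1, 1), 1, 2), r = 300, N = c(1000, 500))
  s20 <- solve_recruitment(pr, order = 20)
  act_spread <- abs(diff(s20$activations))
  s3 <- solve_recruitment(pr, order = 3)
  expect_lt(act_spread, abs(diff(s3$activations)))
})

test_that("infeasible demands raise an insufficient-strength error with the row index", {
  # both muscles push the same way; a negative demand is unreachable
  pr <- recruitment_problem(matrix(c(1, 0.5), 1, 2), r = -10, N = c(1000, 1000))
  err <- tryCatch(solve_recruitment(pr), gaitsens_insufficient_strength = function(e) e)
  expect_s3_class(err, "gaitsens_insufficient_strength")
  expect_identical(err$row, 1L)
})

test_that("trace solving is constant under constant loads and records failures", {
  p <- sample_participant(seed = 2)
  m <- scale_model(reference_model(), p)
  tr <- make_static_trial(n = 7, fy = 700, cop_x = 0.05, angles = 5)
  ld <- inverse_dynamics(tr, m)
  ld$moments[2:6, ] <- rep(ld$moments[4, ], each = 5) # make interior constant
  rt <- solve_trace(ld, m)
  expect_length(rt$failures, 0)
  for (i in 3:6) {
    expect_equal(rt$forces[i, ], rt$forces[2, ], tolerance = 1e-6)
  }
})

test_that("assembled problems have one row per DoF and honour biarticular structure", {
  p <- sample_participant(seed = 3)
  m <- scale_model(reference_model(), p)
  tr <- generate_trial(p, "normal", seed = 5)
  ld <- inverse_dynamics(tr, m)
  pr <- assemble_problem(ld, m, 10)
  expect_identical(dim(pr$C), c(6L, 17L))
  gas <- which(colnames(pr$C) == "gastrocnemius")
  expect_true(pr$C["ankle_pf", gas] != 0 && pr$C["knee_flex", gas] != 0)
  # a muscle with no arm at a joint contributes zero in that row
  sol_col <- which(colnames(pr$C) == "soleus")
  expect_identical(pr$C["knee_flex", sol_col], 0)
})
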