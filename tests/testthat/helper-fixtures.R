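# Shared fixtures and independent oracles used across the suite.

# hand-built stance trial on a small grid; defaults describe quiet standing
# on one leg with the load line through the joint centres
make_static_trial <- function(n = 5, fy = 700, cop_x = 0, cop_z = 0.09,
                              step_width = 0.18, angles = 0) {
  grid <- seq(0, 100, length.out = n)
  fyv <- rep(fy, n); fyv[c(1, n)] <- 0
  gait_trial(
    participant_id = "toy", style = "normal", phase_grid = grid,
    joint_angles = matrix(angles, n, 6),
    grf = cbind(grf_x = rep(0, n), grf_y = fyv, grf_z = rep(0, n)),
    cop = cbind(cop_x = rep(cop_x, n), cop_z = rep(cop_z, n)),
    foot_progression_angle = 5, step_width = step_width,
    speed = 1.16, stance_time = 0.7, trial_index = 1L, seed = 1L
  )
}

# reference model with massless segments (isolates external-load moments)
massless_model <- function() {
  m <- reference_model()
  for (s in names(m$segments)) m$segments[[s]]$mass <- 0
  m
}

# a knee load trace assembled by hand (axial force trace in N, compression
# negative; adduction moment positive loads the medial compartment)
make_load_trace <- function(axial, adduction = 0 * axial, fx = 0 * axial,
                            fz = 0 * axial, meta = list()) {
  n <- length(axial)
  structure(list(
    phase_grid = seq(0, 100, length.out = n),
    knee_flexion_angle = rep(15, n),
    tf_force = cbind(x = fx, y = -abs(axial), z = fz),
    tf_abduction_moment = -adduction,
    tf_rotation_moment = rep(0, n),
    pf_force = cbind(x = rep(0, n), y = rep(0, n), z = rep(0, n)),
    pf_moment = cbind(x = rep(0, n), y = rep(0, n), z = rep(0, n)),
    meta = meta), class = "knee_load_trace")
}

compartment_load <- function(field, geometry, compartment, sample) {
  sum(field$stress[[compartment]][sample, ] * 1e6 * geometry[[compartment]]$area)
}

# independent grid-search oracle for small recruitment problems: the first
# constraint row is all-positive with r1 > 0, so the feasible set is a
# bounded slice; free coordinates are scanned at `step` N and the dependent
# ones solved exactly
grid_search_recruitment <- function(C, r, N, step = 0.1) {
  m <- nrow(C); n <- ncol(C)
  cap <- r[1] / min(C[1, ]) + step
  piv <- seq_len(m)
  B <- C[, piv, drop = FALSE]
  stopifnot(abs(det(B)) > 1e-10)
  free <- setdiff(seq_len(n), piv)
  Bi <- solve(B)
  eval_grid <- function(ffree) {
    # ffree: matrix (points x n_free)
    rhs <- r - if (length(free)) C[, free, drop = FALSE] %*% t(ffree) else
      matrix(0, m, nrow(ffree))
    fdep <- t(Bi %*% rhs)
    f <- matrix(0, nrow(ffree), n)
    f[, piv] <- fdep
    if (length(free)) f[, free] <- ffree
    ok <- rowSums(f < -1e-9) == 0
    f[!ok, ] <- NA
    G <- rowSums((f / rep(N, each = nrow(f)))^3)
    list(f = f, G = G)
  }
  if (length(free) == 0) {
    out <- eval_grid(matrix(0, 1, 0))
    return(out$f[1, ])
  }
  pts <- lapply(free, function(i) seq(0, cap, by = step))
  grid <- as.matrix(expand.grid(pts))
  out <- eval_grid(grid)
  best <- which.min(out$G)
  out$f[best, ]
}

# random bounded recruitment problem for the oracle comparison; the grid
# oracle scans the free coordinates and solves the pivots exactly, so the
# pivot block must be well-conditioned (the grid step would otherwise be
# amplified through the dependent solve beyond the comparison resolution)
random_small_problem <- function() {
  n <- sample(2:3, 1)
  m <- sample(1:min(2, n - 1), 1)
  repeat {
    C <- rbind(matrix(runif(n, 0.5, 1.5), 1, n),
               if (m == 2) matrix(stats::rnorm(n, 0, 1), 1, n))
    if (qr(C)$rank < m) next
    B <- C[, seq_len(m), drop = FALSE]
    if (abs(det(B)) <= 0.3) next
    amp <- if (m < n) max(abs(solve(B, C[, (m + 1):n, drop = FALSE]))) else 0
    if (amp <= 2) break
  }
  r <- c(runif(1, 10, 40), if (m == 2) stats::rnorm(1, 0, 5))
  # strengths kept moderate so the cubic criterion has enough curvature for
  # a 0.1 N grid to resolve the optimum (with very strong muscles the
  # objective is nearly flat and the grid argmin is not meaningful at that
  # resolution; the solver attains a lower criterion value there)
  N <- runif(n, 50, 500)
  list(C = C, r = r, N = N)
}

# classical single-series solution of step-load confined-compression
# consolidation: degree of settlement at normalized time T
consolidation_series <- function(T, n_terms = 300) {
  m <- 0:n_terms
  M <- pi * (2 * m + 1) / 2
  vapply(T, function(tt) 1 - sum(2 / M^2 * exp(-M^2 * tt)), 0)
}

# memoized full default study (several acceptance checks share it)
.study_cache <- new.env(parent = emptyenv())
get_default_study <- function() {
  if (is.null(.study_cache$res)) .study_cache$res <- run_study(default_study_config())
  .study_cache$res
}
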