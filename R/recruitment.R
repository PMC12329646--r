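# Static-optimization muscle recruitment: minimize the polynomial criterion
#   G = sum_i (f_i / N_i)^p        (study order p = 3)
# subject to the moment-balance equalities C f = r and f >= 0. In the scaled
# activation coordinates a_i = f_i / N_i the objective is strictly convex on
# the feasible slice, so the minimizer is unique. No upper bounds f <= N are
# imposed (activations may exceed 1 and are flagged), and there are no
# reserve actuators: an unreachable moment is an explicit error, because
# strength is the experimental variable and silent reserves would mask it.
#
# Solver: primal log-barrier interior point with infeasible-start Newton
# steps (Schur-complement reduction onto the 6 moment equations), followed
# by an active-set polish that re-solves the equality-constrained problem on
# the strictly positive coordinates.

#' Assemble the per-sample recruitment problem
#'
#' One moment-balance row per modeled joint DoF (6 rows); entries of `C` are
#' the muscles' signed moment arms evaluated at the sample's joint angles;
#' `r` is the internal net moment demand at that sample.
#'
#' @param loads a `net_loads`
#' @param model an `msk_model`
#' @param sample_index sample (row) index into the phase grid
#' @param angles optional named joint-angle vector (deg) for arm modulation
#' @return object of class `recruitment_problem` with fields `C`, `r`, `N`,
#'   `n_M`
#' @export
assemble_problem <- function(loads, model, sample_index, angles = NULL) {
  if (sample_index < 1 || sample_index > nrow(loads$moments)) {
    stop_gaitsens("gaitsens_invalid_input", "sample_index outside the phase grid")
  }
  C <- moment_arm_matrix(model, angles)
  # bidirectional actuation must survive any arm modulation, else the
  # problem can silently lose feasibility in one moment direction
  for (i in seq_len(nrow(C))) {
    if (!any(C[i, ] > 0) || !any(C[i, ] < 0)) {
      stop_gaitsens("gaitsens_infeasible_model",
                    sprintf("joint DoF %s lacks bidirectional actuation", rownames(C)[i]))
    }
  }
  N <- muscle_strengths(model)
  recruitment_problem(C, loads$moments[sample_index, ], N)
}

#' Construct and validate a recruitment problem
#'
#' @param C equality-constraint matrix (DoF rows x muscle columns), signed
#'   moment arms in m
#' @param r right-hand side of net moments, N m
#' @param N vector of isometric strengths, N
#' @return object of class `recruitment_problem`
#' @export
recruitment_problem <- function(C, r, N) {
  C <- as.matrix(C)
  if (length(r) != nrow(C) || length(N) != ncol(C)) {
    stop_gaitsens("gaitsens_invalid_input", "inconsistent problem dimensions")
  }
  if (any(!is.finite(C)) || any(!is.finite(r)) || any(!is.finite(N)) || any(N <= 0)) {
    stop_gaitsens("gaitsens_invalid_input", "non-finite entries or non-positive strengths")
  }
  if (qr(C)$rank < nrow(C)) {
    stop_gaitsens("gaitsens_infeasible_model", "constraint matrix is row-rank deficient")
  }
  structure(list(C = C, r = as.numeric(r), N = as.numeric(N), n_M = ncol(C)),
            class = "recruitment_problem")
}

#' Solve the polynomial muscle recruitment problem
#'
#' @param problem a `recruitment_problem`
#' @param tol KKT tolerance (default 1e-8)
#' @param order polynomial order p of the criterion (study value 3)
#' @param warm_start optional activation vector from a neighbouring sample
#' @return object of class `muscle_force_solution`: forces `f` (N),
#'   `activations` (`f/N`, flagged in `over_capacity` when > 1), criterion
#'   value `objective`, Lagrange multipliers `lambda`, and `kkt_residual`
#' @export
solve_recruitment <- function(problem, tol = 1e-8, order = 3, warm_start = NULL) {
  solve_recruitment_impl(problem, tol, order, warm_start)
}

# Schur solve with escalating diagonal regularization: the barrier can pin
# coordinates hard enough that the reduced system loses rank transiently
solve_schur <- function(S, rhs) {
  d <- max(diag(S), 1e-300)
  for (delta in c(0, 1e-12, 1e-9, 1e-6, 1e-3)) {
    out <- tryCatch(solve(S + delta * d * diag(nrow(S)), rhs),
                    error = function(e) NULL)
    if (!is.null(out) && all(is.finite(out))) return(out)
  }
  NULL
}

solve_recruitment_impl <- function(problem, tol = 1e-8, order = 3, warm_start = NULL) {
  C <- problem$C; r <- problem$r; N <- problem$N
  m <- nrow(C); n <- ncol(C); p <- order
  A <- C * rep(N, each = m) # constraint matrix in activation coordinates

  r_scale <- 1 + max(abs(r))
  if (max(abs(r)) < 1e-13) {
    f <- rep(0, n)
    return(new_solution(f, N, C, r, lambda = rep(0, m), p))
  }

  # Feasible-start elastic barrier: slacks u, v >= 0 absorb the moment
  # residual (A a + u - v = r holds exactly from the start, and Newton steps
  # preserve it), a big-M term drives them to zero when the problem is
  # feasible, and the slack diagonal keeps the reduced system full rank.
  a <- if (!is.null(warm_start)) pmax(as.numeric(warm_start), 1e-6) else rep(0.1, n)
  lambda <- rep(0, m)
  mu_seq <- 10^seq(-2, -11, by = -1.5)
  if (!is.null(warm_start)) mu_seq <- 10^seq(-5, -11, by = -2)
  bigM <- 10 * (1 + p * max(pmax(a, 1))^(p - 1))

  for (round in 1:3) {
    rhs0 <- r - as.numeric(A %*% a)
    u <- pmax(rhs0, 0) + 0.1 * r_scale
    v <- u - rhs0
    for (mu in mu_seq) {
      for (iter in 1:40) {
        ga <- p * a^(p - 1) - mu / a
        gu <- bigM - mu / u
        gv <- bigM - mu / v
        ha <- p * (p - 1) * a^(p - 2) + mu / a^2
        hu <- mu / u^2
        hv <- mu / v^2
        AHi <- A * rep(1 / ha, each = m)
        S <- AHi %*% t(A) + diag(1 / hu + 1 / hv, m)
        w <- solve_schur(S, -as.numeric(AHi %*% ga) - gu / hu + gv / hv)
        if (is.null(w)) {
          stop_gaitsens("gaitsens_numerical", "singular KKT system in recruitment solve")
        }
        lambda <- w
        da <- (-ga - as.numeric(crossprod(A, w))) / ha
        du <- (-gu - w) / hu
        dv <- (-gv + w) / hv
        dx <- c(da, du, dv)
        x <- c(a, u, v)
        neg <- dx < 0
        alpha <- if (any(neg)) min(1, 0.995 * min(-x[neg] / dx[neg])) else 1
        phi <- function(aa, uu, vv) sum(aa^p) + bigM * sum(uu + vv) -
          mu * (sum(log(aa)) + sum(log(uu)) + sum(log(vv)))
        phi0 <- phi(a, u, v)
        dder <- sum(c(ga, gu, gv) * dx)
        while (alpha > 1e-13) {
          if (phi(a + alpha * da, u + alpha * du, v + alpha * dv) <=
                phi0 + 1e-4 * alpha * dder) break
          alpha <- alpha / 2
        }
        a <- a + alpha * da
        u <- u + alpha * du
        v <- v + alpha * dv
        if (max(abs(dx)) < 1e-12 * (1 + max(x))) break
      }
    }
    slack <- max(u + v)
    if (slack < 1e-7 * r_scale || round == 3) break
    bigM <- bigM * 100 # slack persists: raise the elastic penalty and retry
  }

  if (max(abs(r - as.numeric(A %*% a))) > 1e-6 * r_scale) {
    worst <- which.max(abs(r - as.numeric(A %*% a)))
    stop_gaitsens("gaitsens_insufficient_strength",
                  sprintf("required moment unreachable with nonnegative forces (row %d)", worst),
                  row = worst)
  }

  # Active-set polish: exact Newton on the equality-constrained problem
  # restricted to the strictly positive coordinates. A coordinate driven to
  # its bound is deactivated; a bound coordinate whose reduced gradient
  # turns profitable is reactivated. The problem is strictly convex on the
  # slice, so these exchanges terminate.
  a_bar <- a
  lambda_bar <- lambda
  free <- a > max(a) * 1e-7
  for (rounds in 1:30) {
    if (sum(free) < m) break
    Af <- A[, free, drop = FALSE]
    if (qr(Af)$rank < m) break
    af <- pmax(a[free], 1e-12)
    dropped <- FALSE
    for (k in 1:30) {
      grad <- p * af^(p - 1)
      h <- pmax(p * (p - 1) * af^(p - 2), 1e-300)
      rp <- r - as.numeric(Af %*% af)
      AHi <- Af * rep(1 / h, each = m)
      S <- AHi %*% t(Af)
      lam <- solve_schur(S, as.numeric(AHi %*% grad) + rp)
      if (is.null(lam)) break
      da <- (-grad + as.numeric(crossprod(Af, lam))) / h
      ratio <- ifelse(da < 0, -af / da, Inf)
      amax <- min(ratio)
      if (amax <= 1) { # blocked: step to the bound and deactivate blockers
        af <- pmax(af + amax * da, 0)
        blk <- which(ratio <= amax * (1 + 1e-9))
        a[free] <- af
        idx <- which(free)[blk]
        a[idx] <- 0
        free[idx] <- FALSE
        dropped <- TRUE
        break
      }
      af <- af + da
      lambda <- lam
      if (max(abs(da)) < 1e-14 * (1 + max(af))) break
    }
    if (dropped) next
    if (!all(af > 0) ||
        max(abs(r - as.numeric(Af %*% af))) >
          max(abs(r - as.numeric(A %*% a_bar))) + 1e-9 * r_scale) {
      a <- a_bar
      lambda <- lambda_bar
      break
    }
    a[free] <- af
    a[!free] <- 0
    # multipliers from exact stationarity on the free set (least squares)
    lambda <- tryCatch(qr.solve(t(Af), p * af^(p - 1)), error = function(e) lambda)
    # reduced gradient on the bound coordinates: negative means activating
    # that muscle would lower the criterion -> bring it back in
    s_bound <- -as.numeric(crossprod(A, lambda))
    viol <- which(!free & s_bound < -1e-10 * (1 + max(abs(p * af^(p - 1)))))
    if (length(viol) == 0) break
    add <- viol[which.min(s_bound[viol])]
    free[add] <- TRUE
    a[add] <- 1e-3 * max(af)
  }
  if (sum(free) < m) { # polish abandoned: fall back to the barrier iterate
    a <- a_bar
    lambda <- lambda_bar
  }

  f <- a * N
  new_solution(f, N, C, r, lambda, p)
}

# package a solution with its KKT certificate
new_solution <- function(f, N, C, r, lambda, p) {
  a <- f / N
  A <- C * rep(N, each = nrow(C))
  grad <- p * a^(p - 1)
  s <- grad - as.numeric(crossprod(A, lambda)) # stationarity residual in a-coords
  scale <- 1 + max(abs(grad))
  kkt <- max(
    max(abs(as.numeric(C %*% f) - r)) / (1 + max(abs(r))),
    max(abs(a * s)) / scale,        # complementarity
    max(0, -s) / scale              # dual feasibility at the bound
  )
  structure(
    list(f = f, activations = a, objective = sum(a^p),
         lambda = lambda, kkt_residual = kkt, order = p,
         over_capacity = a > 1),
    class = "muscle_force_solution"
  )
}

#' @export
print.muscle_force_solution <- function(x, ...) {
  cat(sprintf("<muscle_force_solution>  G = %.4g, max activation %.3f, KKT %.2g\n",
              x$objective, max(x$activations), x$kkt_residual))
  invisible(x)
}

#' Solve recruitment across the whole stance phase
#'
#' Independent per-sample solves, warm-started sequentially. Failures are
#' recorded per sample with their error class rather than aborting the
#' trace.
#'
#' @param loads a `net_loads`
#' @param model an `msk_model`
#' @param trial optional [gait_trial()] supplying joint angles for
#'   angle-modulated moment arms
#' @param tol,order passed to [solve_recruitment()]
#' @return object of class `recruitment_trace`: force matrix (samples x
#'   muscles), activation matrix, objective and KKT vectors, and `failures`
#' @export
solve_trace <- function(loads, model, trial = NULL, tol = 1e-8, order = 3) {
  n <- nrow(loads$moments)
  nm <- length(model$muscles)
  mus_names <- vapply(model$muscles, `[[`, "", "name")
  fmat <- matrix(NA_real_, n, nm, dimnames = list(NULL, mus_names))
  amat <- fmat
  obj <- rep(NA_real_, n)
  kkt <- rep(NA_real_, n)
  failures <- list()
  warm <- NULL
  for (i in seq_len(n)) {
    angles <- if (!is.null(trial)) trial$joint_angles[i, ] else NULL
    sol <- tryCatch({
      prob <- assemble_problem(loads, model, i, angles)
      solve_recruitment(prob, tol = tol, order = order, warm_start = warm)
    }, gaitsens_error = function(e) e)
    if (inherits(sol, "muscle_force_solution")) {
      fmat[i, ] <- sol$f
      amat[i, ] <- sol$activations
      obj[i] <- sol$objective
      kkt[i] <- sol$kkt_residual
      warm <- pmax(sol$activations, 1e-6)
    } else {
      failures[[length(failures) + 1L]] <-
        list(sample = i, class = class(sol)[1], message = conditionMessage(sol))
      warm <- NULL
    }
  }
  structure(
    list(phase_grid = loads$phase_grid, forces = fmat, activations = amat,
         objective = obj, kkt_residual = kkt, failures = failures),
    class = "recruitment_trace"
  )
}

#' @export
print.recruitment_trace <- function(x, ...) {
  cat(sprintf("<recruitment_trace>  %d samples x %d muscles, %d failures, max KKT %.2g\n",
              nrow(x$forces), ncol(x$forces), length(x$failures),
              suppressWarnings(max(x$kkt_residual, na.rm = TRUE))))
  invisible(x)
}

#' Write a recruitment trace to CSV (one column per muscle)
#' @param trace a `recruitment_trace`
#' @param path output path
#' @param what `"forces"` (N) or `"activations"`
#' @export
write_recruitment_trace <- function(trace, path, what = c("forces", "activations")) {
  what <- match.arg(what)
  df <- data.frame(phase = trace$phase_grid, trace[[what]])
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
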