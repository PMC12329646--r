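# One-dimensional biphasic (linear poroelastic) cartilage column in confined
# compression: a solid matrix of aggregate modulus H_A saturated with fluid
# of permeability k. Pore pressure obeys the consolidation equation
#   dp/dt = H_A k d2p/dz2  (+ dsigma/dt for a time-varying surface traction)
# with a free-draining loaded surface (p = 0 at z = 0) and an impermeable
# rigid base (dp/dz = 0 at z = h). Surface settlement follows from the
# effective stress: u(t) = (sigma(t) h - integral p dz) / H_A.
#
# The module verifies consolidation physics against the classical series
# solution and calibrates the rate-dependent effective foundation modulus
# used by the contact stage.

#' Construct a biphasic cartilage column
#'
#' Default parameters (aggregate modulus 0.5 MPa, permeability
#' 2e-15 m^4/(N s), thickness 3 mm) are generic adult articular-cartilage
#' values from config, not measured quantities.
#'
#' @param thickness m
#' @param aggregate_modulus Pa
#' @param permeability m^4/(N s)
#' @param n_nodes number of grid nodes (>= 20)
#' @return object of class `biphasic_column`
#' @export
biphasic_column <- function(thickness = 0.003, aggregate_modulus = 0.5e6,
                            permeability = 2e-15, n_nodes = 100) {
  if (thickness <= 0 || aggregate_modulus <= 0 || permeability <= 0) {
    stop_gaitsens("gaitsens_invalid_configuration",
                  "column physical parameters must be positive")
  }
  if (n_nodes < 20) stop_gaitsens("gaitsens_invalid_configuration", "need n_nodes >= 20")
  structure(
    list(thickness = thickness, aggregate_modulus = aggregate_modulus,
         permeability = permeability, n_nodes = as.integer(n_nodes),
         # consolidation coefficient and characteristic time
         c_v = aggregate_modulus * permeability,
         t_star = thickness^2 / (aggregate_modulus * permeability)),
    class = "biphasic_column"
  )
}

#' @export
print.biphasic_column <- function(x, ...) {
  cat(sprintf("<biphasic_column>  h %.1f mm, H_A %.2f MPa, k %.2g m^4/(N s), t* %.3g s\n",
              1000 * x$thickness, x$aggregate_modulus / 1e6, x$permeability, x$t_star))
  invisible(x)
}

# backward-Euler operator pieces: interior second differences, p = 0 at the
# surface node, mirrored ghost at the impermeable base
consolidation_matrix <- function(n, dz, c_v, dt) {
  r <- c_v * dt / dz^2
  A <- diag(1 + 2 * r, n)
  for (i in 2:n) A[i, i - 1] <- -r
  for (i in 1:(n - 1)) A[i, i + 1] <- -r
  # node 1 sits one dz inside the drained surface: p(0) = 0 is the absorbed
  # boundary (no correction needed); node n has dp/dz = 0: mirrored ghost
  A[n, n - 1] <- -2 * r
  A
}

#' Simulate ramp-hold confined-compression consolidation
#'
#' Implicit (backward-Euler) finite differences on the pore-pressure field;
#' the surface traction ramps linearly to `sigma0` over `ramp_time` (0 for a
#' step load) and is then held.
#'
#' @param column a [biphasic_column()]
#' @param sigma0 surface traction, Pa
#' @param duration simulated time, s
#' @param dt time step, s; must satisfy `dt <= 0.4 dz^2 / (H_A k)`
#' @param ramp_time ramp duration, s
#' @return list with `time`, `settlement` (m), `sigma` (applied traction
#'   trace), `pressure` (time x node matrix, Pa), `z` (node depths, m)
#' @export
simulate_consolidation <- function(column, sigma0, duration, dt, ramp_time = 0) {
  h <- column$thickness
  n <- column$n_nodes
  dz <- h / n # node i at depth i * dz; surface boundary absorbed, base at z = h
  if (dt > 0.4 * dz^2 / column$c_v) {
    stop_gaitsens("gaitsens_invalid_configuration",
                  sprintf("dt exceeds the stable step 0.4 dz^2/(H_A k) = %.3g s",
                          0.4 * dz^2 / column$c_v))
  }
  steps <- max(1L, ceiling(duration / dt))
  A <- consolidation_matrix(n, dz, column$c_v, dt)
  Ai <- solve(A)
  p <- rep(0, n)
  sigma_old <- 0
  times <- numeric(steps)
  settlement <- numeric(steps)
  sigma_tr <- numeric(steps)
  pressure <- matrix(0, steps, n)
  for (s in seq_len(steps)) {
    t_now <- s * dt
    sigma_now <- if (ramp_time > 0) sigma0 * min(t_now / ramp_time, 1) else sigma0
    # a load increment is carried instantaneously by the fluid
    p <- as.numeric(Ai %*% (p + (sigma_now - sigma_old)))
    if (any(!is.finite(p))) {
      stop_gaitsens("gaitsens_numerical",
                    sprintf("consolidation diverged at step %d (dt = %.3g s)", s, dt))
    }
    sigma_old <- sigma_now
    # trapezoid over [0, h] with p(0) = 0
    int_p <- dz * (sum(p) - p[n] / 2)
    times[s] <- t_now
    settlement[s] <- (sigma_now * h - int_p) / column$aggregate_modulus
    sigma_tr[s] <- sigma_now
    pressure[s, ] <- p
  }
  list(time = times, settlement = settlement, sigma = sigma_tr,
       pressure = pressure, z = (seq_len(n)) * dz)
}

#' Rate-dependent effective foundation modulus
#'
#' Displacement-controlled ramp of the column to 10% strain over
#' `loading_timescale`; returns the stress/strain ratio at the end of the
#' ramp. Slow ramps drain fully and recover the aggregate modulus H_A;
#' fast ramps trap the fluid and stiffen the response, which is what the
#' elastic-foundation contact stage needs as its effective modulus at gait
#' loading rates.
#'
#' @param column a [biphasic_column()]
#' @param loading_timescale ramp duration, s
#' @param target_strain ramp strain (default 0.10)
#' @return effective modulus, Pa
#' @export
effective_foundation_modulus <- function(column, loading_timescale,
                                         target_strain = 0.10) {
  if (!is.finite(loading_timescale) || loading_timescale <= 0) {
    stop_gaitsens("gaitsens_invalid_configuration", "loading_timescale must be > 0")
  }
  h <- column$thickness
  n <- column$n_nodes
  dz <- h / n
  dt <- min(loading_timescale / 200, 0.4 * dz^2 / column$c_v)
  steps <- ceiling(loading_timescale / dt)
  A <- consolidation_matrix(n, dz, column$c_v, dt)
  # displacement control couples sigma to p through
  #   sigma = (H_A u(t) + integral p dz) / h;
  # eliminate sigma from the backward-Euler update A p_new - 1 sigma_new =
  # p_old - sigma_old
  w <- rep(dz, n); w[n] <- dz / 2 # trapezoid weights (surface term is 0)
  M <- A - matrix(1, n, 1) %*% matrix(w / h, 1, n)
  Mi <- solve(M)
  p <- rep(0, n)
  sigma_old <- 0
  for (s in seq_len(steps)) {
    t_now <- min(s * dt, loading_timescale)
    u_t <- target_strain * h * (t_now / loading_timescale)
    p <- as.numeric(Mi %*% (p - sigma_old + column$aggregate_modulus * u_t / h))
    sigma_old <- (column$aggregate_modulus * u_t + sum(w * p)) / h
  }
  sigma_old / target_strain
}
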