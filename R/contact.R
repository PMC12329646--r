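# Connector-restrained elastic-foundation contact on the tibial plateaus.
#
# The cartilage layer on each compartment is a bed of independent springs
# (foundation modulus from the biphasic calibration or config); the femoral
# condyles are paraboloid caps over the compartment centres. Per sample, the
# femur pose (axial penetration, ab-ad rotation, AP and ML translation; knee
# flexion prescribed, internal-external rotation held by its connector at
# the linearised equilibrium) is found by damped Newton iteration so that
# integrated element pressures plus connector loads balance the applied
# tibiofemoral force and frontal moment. Superficial contact pressure is
# used as the surrogate for the maximum principal stress magnitude.

#' Rectangular-grid tibial plateau geometry
#'
#' Two compartments (medial at -z, lateral at +z), each an `nx x nz` element
#' grid over a `plate_x` by `plate_z` rectangle. Defaults (8 x 8 elements,
#' 20 x 15 mm plates, 40 mm intercondylar spacing, 3 mm cartilage) are
#' configuration values.
#'
#' @param nx,nz elements per compartment in x and z (product >= 64)
#' @param plate_x,plate_z plateau extents, m
#' @param spacing intercondylar spacing between compartment load centres, m
#' @param thickness cartilage thickness, m
#' @param modulus effective foundation modulus, Pa (scalar or per-compartment
#'   named vector `c(medial=, lateral=)`)
#' @param poisson Poisson ratio used in the foundation formula
#' @param condyle_rx,condyle_rz paraboloid condyle radii, m
#' @param dish_rx,dish_rz tibial dish (concavity) radii per compartment, m;
#'   the dish tilts the element normals inward, letting contact resist
#'   AP/ML shear globally
#' @param shear_coupling tangential compliance of the cartilage layer, 1/m:
#'   each unit of normal force resists tangential translation u with force
#'   `shear_coupling * u` (thin bonded elastic layer, G / (E t) scaling);
#'   `NULL` computes `1 / (2 (1 + poisson) thickness)`
#' @return object of class `plateau_geometry`
#' @export
plateau_geometry <- function(nx = 8, nz = 8, plate_x = 0.020, plate_z = 0.015,
                             spacing = 0.040, thickness = 0.003,
                             modulus = 20e6, poisson = 0.42,
                             condyle_rx = 0.035, condyle_rz = 0.045,
                             dish_rx = 0.055, dish_rz = 0.070,
                             shear_coupling = NULL) {
  if (nx * nz < 64) stop_gaitsens("gaitsens_invalid_configuration",
                                  "need >= 64 elements per compartment")
  if (thickness <= 0 || plate_x <= 0 || plate_z <= 0 || any(modulus <= 0)) {
    stop_gaitsens("gaitsens_invalid_configuration", "geometry parameters must be positive")
  }
  if (plate_z >= spacing) stop_gaitsens("gaitsens_invalid_configuration",
                                        "compartment grids would overlap")
  if (dish_rx <= condyle_rx || dish_rz <= condyle_rz) {
    stop_gaitsens("gaitsens_invalid_configuration",
                  "dish radii must exceed condyle radii (non-conforming gap)")
  }
  if (is.null(shear_coupling)) {
    shear_coupling <- 1 / (2 * (1 + poisson) * thickness)
  }
  mod <- if (length(modulus) == 2) modulus else c(medial = modulus, lateral = modulus)
  xs <- (seq_len(nx) - 0.5) / nx * plate_x - plate_x / 2
  zs <- (seq_len(nz) - 0.5) / nz * plate_z - plate_z / 2
  grid <- expand.grid(x = xs, dz = zs)
  area <- (plate_x / nx) * (plate_z / nz)
  comp <- function(name, zc) {
    list(name = name, x = grid$x, z = zc + grid$dz, z_center = zc,
         area = rep(area, nrow(grid)), thickness = thickness,
         modulus = unname(mod[[name]]))
  }
  structure(
    list(medial = comp("medial", -spacing / 2),
         lateral = comp("lateral", spacing / 2),
         spacing = spacing, poisson = poisson,
         condyle_rx = condyle_rx, condyle_rz = condyle_rz,
         dish_rx = dish_rx, dish_rz = dish_rz,
         shear_coupling = shear_coupling,
         thickness = thickness),
    class = "plateau_geometry"
  )
}

#' Connector restraint stiffnesses
#'
#' Linear springs standing in for the unmodeled soft tissues that restrain
#' secondary knee kinematics. Defaults: tibiofemoral AP/ML translation
#' 0.5 N/mm, internal-external rotation 1.2 Nm/degree, patellar ML
#' translation 0.2 N/mm, patellar rotations 0.9 Nm/degree (stored exactly in
#' these mixed units, converted internally).
#'
#' @param tf_translation N/mm, tibiofemoral AP and ML translation
#' @param tf_rotation Nm/degree, tibiofemoral internal-external rotation
#' @param patellar_translation N/mm, patellar ML translation
#' @param patellar_rotation Nm/degree, patellar rotations
#' @return object of class `connector_set`
#' @export
connector_set <- function(tf_translation = 0.5, tf_rotation = 1.2,
                          patellar_translation = 0.2, patellar_rotation = 0.9) {
  vals <- c(tf_translation, tf_rotation, patellar_translation, patellar_rotation)
  if (any(vals < 0)) stop_gaitsens("gaitsens_invalid_configuration",
                                   "connector stiffnesses must be >= 0")
  structure(
    list(tf_translation_stiffness = tf_translation,
         tf_rotation_stiffness = tf_rotation,
         patellar_translation_stiffness = patellar_translation,
         patellar_rotation_stiffness = patellar_rotation),
    class = "connector_set"
  )
}

# foundation stiffness per element, Pa/m: confined-compression modulus of a
# thin layer, E (1-nu) / ((1+nu)(1-2nu) t)
foundation_k <- function(comp, poisson) {
  comp$modulus * (1 - poisson) / ((1 + poisson) * (1 - 2 * poisson) * comp$thickness)
}

# element penetrations for pose q = (uy, theta, ux, uz); the gap is the
# space between the paraboloid condyle and the (fixed) concave tibial dish
# of each compartment: conforming surfaces flatten the gap
penetrations <- function(q, comp, geom) {
  gap <- (comp$x - q[3])^2 / (2 * geom$condyle_rx) +
    (comp$z - comp$z_center - q[4])^2 / (2 * geom$condyle_rz) -
    comp$x^2 / (2 * geom$dish_rx) -
    (comp$z - comp$z_center)^2 / (2 * geom$dish_rz)
  q[1] - q[2] * comp$z - gap
}

# contact contributions of one compartment to the 4-DoF residual; element
# forces act along the local dish normal, so their horizontal components
# (slope x force) resist AP/ML shear
comp_forces <- function(q, comp, geom, eps = 0) {
  pen <- ramp_plus(penetrations(q, comp, geom), eps)
  k <- foundation_k(comp, geom$poisson)
  fe <- k * pen * comp$area # element normal forces, N
  c(Fy = sum(fe),
    Mx = -sum(fe * comp$z),
    Fx = sum(fe * comp$x / geom$dish_rx),
    Fz = sum(fe * (comp$z - comp$z_center) / geom$dish_rz))
}

# smoothed positive part: softplus with width eps (eps = 0 is the exact
# kink); used for continuation when an equilibrium sits on a contact-set
# boundary
ramp_plus <- function(x, eps) {
  if (eps <= 0) return(pmax(x, 0))
  ifelse(x / eps > 30, x, eps * log1p(exp(pmin(x / eps, 30))))
}

contact_residual <- function(q, applied, geom, connectors, eps = 0) {
  k_t <- connectors$tf_translation_stiffness * 1000 # N/mm -> N/m
  fc <- comp_forces(q, geom$medial, geom, eps) + comp_forces(q, geom$lateral, geom, eps)
  k_shear <- geom$shear_coupling * fc[["Fy"]] # pressure-proportional layer shear
  c(applied["Fy"] - fc["Fy"],
    applied["Mx"] - fc["Mx"],
    applied["Fx"] - fc["Fx"] - (k_t + k_shear) * q[3],
    applied["Fz"] - fc["Fz"] - (k_t + k_shear) * q[4])
}

# damped Newton with finite-difference Jacobian on the 4-DoF residual;
# equilibria near compartment lift-off sit on a contact-set kink where plain
# Newton can stall, so failures retry with continuation on the shear/moment
# loads (warm-starting each leg)
solve_pose <- function(applied, geom, connectors, q0 = NULL, tol_rel = 1e-6,
                       max_iter = 100) {
  sol <- solve_pose_once(applied, geom, connectors, q0, tol_rel, max_iter)
  if (!is.null(sol)) return(sol)
  q <- q0
  for (eps in c(1e-4, 1e-5, 1e-6, 1e-7, 0)) {
    sol <- solve_pose_once(applied, geom, connectors, q, tol_rel, max_iter,
                           eps = eps)
    if (is.null(sol)) break
    q <- sol$q
  }
  if (is.null(sol)) {
    stop_gaitsens("gaitsens_convergence",
                  sprintf("contact Newton did not converge in %d iterations", max_iter))
  }
  sol
}

solve_pose_once <- function(applied, geom, connectors, q0 = NULL, tol_rel = 1e-6,
                            max_iter = 100, eps = 0) {
  scale <- max(abs(applied["Fy"]), 1) # N
  q <- if (is.null(q0)) c(1e-5, 0, 0, 0) else q0
  h <- c(1e-9, 1e-9, 1e-9, 1e-9)
  wt <- c(1, 1 / (geom$spacing / 2), 1, 1) # moment residual in force units
  res <- contact_residual(q, applied, geom, connectors, eps)
  lam <- 1e-3
  for (iter in seq_len(max_iter)) {
    if (max(abs(res * wt)) <= tol_rel * scale) {
      return(list(q = q, residual = max(abs(res * wt)) / scale))
    }
    J <- matrix(0, 4, 4)
    for (j in 1:4) {
      qj <- q; qj[j] <- qj[j] + h[j]
      J[, j] <- (contact_residual(qj, applied, geom, connectors, eps) - res) / h[j]
    }
    A <- crossprod(J * wt)
    g <- as.numeric(crossprod(J * wt, res * wt))
    D <- diag(pmax(diag(A), 1e-30), 4)
    if (all(abs(g) < 1e-300)) { # no contact yet and flat: push into contact
      q[1] <- q[1] + geom$thickness / 10
      res <- contact_residual(q, applied, geom, connectors, eps)
      next
    }
    n0 <- sum((res * wt)^2)
    accepted <- FALSE
    for (k in 1:25) { # Levenberg-Marquardt damping loop
      dq <- tryCatch(-solve(A + lam * D, g), error = function(e) NULL)
      if (!is.null(dq)) {
        rn <- contact_residual(q + dq, applied, geom, connectors, eps)
        if (sum((rn * wt)^2) < n0) {
          q <- q + dq
          res <- rn
          lam <- max(lam / 3, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lam <- lam * 10
    }
    if (!accepted) return(NULL)
  }
  if (max(abs(res * wt)) <= tol_rel * scale) {
    return(list(q = q, residual = max(abs(res * wt)) / scale))
  }
  NULL
}

#' Solve elastic-foundation contact over a knee load trace
#'
#' Per sample the applied loads are the axial compression, the AP/ML shear
#' components and the frontal (adduction) moment from the trace; a
#' compressive axial force <= 0 (lift-off) yields a zero field for that
#' sample rather than an error.
#'
#' @param trace a `knee_load_trace`
#' @param geometry a [plateau_geometry()]
#' @param connectors a [connector_set()]
#' @return object of class `stress_field`: per-compartment element stress
#'   matrices (samples x elements, MPa), contact masks, femur poses and
#'   equilibrium residuals
#' @export
solve_contact <- function(trace, geometry, connectors = connector_set()) {
  n <- length(trace$phase_grid)
  n_el <- length(geometry$medial$x)
  stress <- list(medial = matrix(0, n, n_el), lateral = matrix(0, n, n_el))
  pose <- matrix(0, n, 5,
                 dimnames = list(NULL, c("penetration", "abad_rot", "ap_trans",
                                         "ml_trans", "ie_rot")))
  residual <- numeric(n)
  k_rot <- connectors$tf_rotation_stiffness * 180 / pi # Nm/deg -> Nm/rad
  q_warm <- NULL
  for (i in seq_len(n)) {
    f_axial <- -trace$tf_force[i, "y"] # compression, positive
    if (!is.finite(f_axial) || f_axial <= 0) next # lift-off: zero field
    applied <- c(Fy = unname(f_axial),
                 Mx = -unname(trace$tf_abduction_moment[i]), # adduction positive
                 Fx = unname(trace$tf_force[i, "x"]),
                 Fz = unname(trace$tf_force[i, "z"]))
    sol <- solve_pose(applied, geometry, connectors, q0 = q_warm)
    q_warm <- sol$q
    pose[i, 1:4] <- sol$q
    pose[i, 5] <- if (k_rot > 0) trace$tf_rotation_moment[i] / k_rot else 0
    residual[i] <- sol$residual
    for (cn in c("medial", "lateral")) {
      comp <- geometry[[cn]]
      pen <- pmax(penetrations(sol$q, comp, geometry), 0)
      stress[[cn]][i, ] <- foundation_k(comp, geometry$poisson) * pen / 1e6
    }
  }
  structure(
    list(phase_grid = trace$phase_grid, stress = stress,
         mask = lapply(stress, function(s) s > 0),
         pose = pose, residual = residual, meta = trace$meta),
    class = "stress_field"
  )
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("<stress_field>  %d samples; peak stress medial %.2f / lateral %.2f MPa\n",
              length(x$phase_grid), max(x$stress$medial), max(x$stress$lateral)))
  invisible(x)
}

#' Upper-quartile mean stress summary
#'
#' Per compartment and sample: restrict to the elements in contact, rank by
#' stress, and average the top `ceil(0.25 * n_contact)` elements — the mean
#' of the upper quartile of superficial stress over the contact area. Empty
#' contact yields 0 and is flagged.
#'
#' @param field a `stress_field`
#' @return object of class `stress_summary`: per-compartment time series
#'   (MPa), peak values and peak phases, and `no_contact` flags
#' @export
upper_quartile_summary <- function(field) {
  out <- list()
  flags <- list()
  for (cn in c("medial", "lateral")) {
    s <- field$stress[[cn]]
    uq <- apply(s, 1, function(row) {
      contact <- row[row > 0]
      if (length(contact) == 0) return(0)
      k <- ceiling(0.25 * length(contact))
      mean(sort(contact, decreasing = TRUE)[seq_len(k)])
    })
    out[[cn]] <- uq
    flags[[cn]] <- apply(s, 1, function(row) !any(row > 0))
  }
  peaks <- lapply(out, function(u) {
    i <- which.max(u)
    c(value = u[i], phase = field$phase_grid[i])
  })
  structure(
    list(phase_grid = field$phase_grid,
         medial = out$medial, lateral = out$lateral,
         peak = peaks, no_contact = flags, meta = field$meta),
    class = "stress_summary"
  )
}

#' @export
print.stress_summary <- function(x, ...) {
  cat(sprintf("<stress_summary>  peak medial %.2f MPa @ %.0f%%, lateral %.2f MPa @ %.0f%%\n",
              x$peak$medial["value"], x$peak$medial["phase"],
              x$peak$lateral["value"], x$peak$lateral["phase"]))
  invisible(x)
}

#' Write a stress summary to CSV
#' @param summary a `stress_summary`
#' @param path output path
#' @export
write_stress_summary <- function(summary, path) {
  df <- data.frame(phase = summary$phase_grid, medial = summary$medial,
                   lateral = summary$lateral)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
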