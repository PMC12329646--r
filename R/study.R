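# Full-study orchestration: synthetic cohort -> inverse dynamics ->
# recruitment under four strength conditions -> per-style averaged knee
# loads -> elastic-foundation contact -> upper-quartile stress summaries ->
# percent-change / percentage-point sensitivity statistics and tests.

# fast per-sample problem construction for a fixed model (constant arms):
# skips per-sample validation, which trace-level assembly already did once
fast_trace <- function(loads, model, tol, order) {
  C <- moment_arm_matrix(model)
  for (i in seq_len(nrow(C))) {
    if (!any(C[i, ] > 0) || !any(C[i, ] < 0)) {
      stop_gaitsens("gaitsens_infeasible_model",
                    sprintf("joint DoF %s lacks bidirectional actuation", rownames(C)[i]))
    }
  }
  N <- muscle_strengths(model)
  n <- nrow(loads$moments)
  fmat <- matrix(NA_real_, n, length(N), dimnames = list(NULL, names(N)))
  amat <- fmat
  obj <- rep(NA_real_, n)
  kkt <- rep(NA_real_, n)
  failures <- list()
  warm <- NULL
  for (i in seq_len(n)) {
    prob <- structure(list(C = C, r = loads$moments[i, ], N = N, n_M = ncol(C)),
                      class = "recruitment_problem")
    sol <- tryCatch(solve_recruitment(prob, tol = tol, order = order, warm_start = warm),
                    gaitsens_error = function(e) e)
    if (inherits(sol, "muscle_force_solution")) {
      fmat[i, ] <- sol$f; amat[i, ] <- sol$activations
      obj[i] <- sol$objective; kkt[i] <- sol$kkt_residual
      warm <- pmax(sol$activations, 1e-6)
    } else {
      failures[[length(failures) + 1L]] <-
        list(sample = i, class = class(sol)[1], message = conditionMessage(sol))
      warm <- NULL
    }
  }
  structure(list(phase_grid = loads$phase_grid, forces = fmat, activations = amat,
                 objective = obj, kkt_residual = kkt, failures = failures),
            class = "recruitment_trace")
}

#' Run the complete sensitivity study on a synthetic cohort
#'
#' Orchestrates the full pipeline for every (participant, style, strength
#' condition) cell: five generated trials are analyzed through inverse
#' dynamics and cubic-criterion recruitment, their knee load traces are
#' averaged per style, contact is solved per condition, and the
#' upper-quartile stress summaries feed the percent-change (reduced vs
#' reference strength) and percentage-point (modified vs normal gait)
#' statistics, cohort aggregation, paired t tests on peak stresses and the
#' repeated-measures ANOVA on walking speeds. Cell-level failures are
#' recorded and the study continues.
#'
#' @param config configuration list from [load_config()] /
#'   [default_study_config()]
#' @return object of class `study_result` (tidy data frames `stress`,
#'   `percent_change`, `pp_difference`, `peaks`, `speeds`, `late_stance`,
#'   plus `tests`, `cohort`, `manifest`, `config`)
#' @export
run_study <- function(config = default_study_config()) {
  config <- validate_config(config)
  cohort <- generate_cohort(config$n_participants, config$n_trials,
                            config$styles, config$master_seed,
                            config$cohort, config$generator)
  ref <- reference_model(config$reference_model$mass,
                         config$reference_model$height,
                         config$reference_model$fat_fraction,
                         arm_cosine_modulation = config$reference_model$arm_cosine_modulation)

  # foundation modulus: biphasic calibration at the gait loading timescale
  modulus <- config$contact$modulus
  if (is.null(modulus)) {
    col <- biphasic_column(config$cartilage$thickness,
                           config$cartilage$aggregate_modulus,
                           config$cartilage$permeability,
                           config$cartilage$n_nodes)
    modulus <- effective_foundation_modulus(col, config$contact$loading_timescale)
  }
  geometry <- plateau_geometry(
    nx = config$contact$nx, nz = config$contact$nz,
    plate_x = config$contact$plate_x, plate_z = config$contact$plate_z,
    spacing = config$contact$spacing, thickness = config$contact$thickness,
    modulus = modulus, poisson = config$contact$poisson,
    condyle_rx = config$contact$condyle_rx, condyle_rz = config$contact$condyle_rz,
    dish_rx = config$contact$dish_rx, dish_rz = config$contact$dish_rz)
  connectors <- connector_set(config$connectors$tf_translation,
                              config$connectors$tf_rotation,
                              config$connectors$patellar_translation,
                              config$connectors$patellar_rotation)

  conditions <- c("reference", config$strength_groups)
  failures <- list()
  stress_rows <- list()
  speeds_rows <- list()
  summaries <- list() # [[pid]][[style]][[condition]] -> stress_summary

  for (p in cohort$participants) {
    model_p <- scale_model(ref, p)
    models <- c(list(reference = model_p),
                stats::setNames(
                  lapply(config$strength_groups, function(g) {
                    reduce_strength(model_p, g, config$strength_fraction)
                  }), config$strength_groups))
    trials_p <- Filter(function(tr) tr$participant_id == p$id, cohort$trials)
    summaries[[p$id]] <- list()
    for (st in config$styles) {
      trials_s <- Filter(function(tr) tr$style == st, trials_p)
      speeds_rows[[length(speeds_rows) + 1L]] <- data.frame(
        participant = p$id, style = st,
        trial = vapply(trials_s, `[[`, 0L, "trial_index"),
        speed = vapply(trials_s, `[[`, 0, "speed"))
      loads_s <- lapply(trials_s, inverse_dynamics, model = model_p,
                        mode = config$dynamics_mode, params = config$dynamics)
      summaries[[p$id]][[st]] <- list()
      for (cond in conditions) {
        cell <- tryCatch({
          traces <- lapply(seq_along(trials_s), function(k) {
            rt <- fast_trace(loads_s[[k]], models[[cond]],
                             config$recruitment$tol, config$recruitment$order)
            assemble_knee_loads(trials_s[[k]], loads_s[[k]], rt, models[[cond]],
                                config$kneeload,
                                meta = list(participant = p$id, style = st,
                                            condition = cond))
          })
          avg <- average_traces(traces)
          field <- solve_contact(avg, geometry, connectors)
          upper_quartile_summary(field)
        }, gaitsens_error = function(e) e)
        if (inherits(cell, "stress_summary")) {
          summaries[[p$id]][[st]][[cond]] <- cell
          stress_rows[[length(stress_rows) + 1L]] <- data.frame(
            participant = p$id, style = st, condition = cond,
            phase = cell$phase_grid, medial = cell$medial, lateral = cell$lateral)
        } else {
          failures[[length(failures) + 1L]] <- list(
            participant = p$id, style = st, condition = cond,
            class = class(cell)[1], message = conditionMessage(cell))
        }
      }
    }
  }

  stress <- do.call(rbind, stress_rows)
  speeds <- do.call(rbind, speeds_rows)

  # Eq. 2 / Eq. 3 statistics per participant
  pc_rows <- list(); pp_rows <- list(); peak_rows <- list(); late_rows <- list()
  lw <- config$late_stance_window
  for (pid in names(summaries)) {
    for (st in names(summaries[[pid]])) {
      cell <- summaries[[pid]][[st]]
      if (is.null(cell$reference)) next
      phase <- cell$reference$phase_grid
      for (cond in conditions) {
        if (is.null(cell[[cond]])) next
        for (comp in c("medial", "lateral")) {
          peak_rows[[length(peak_rows) + 1L]] <- data.frame(
            participant = pid, style = st, condition = cond, compartment = comp,
            peak = max(cell[[cond]][[comp]]),
            peak_phase = phase[which.max(cell[[cond]][[comp]])])
        }
        if (cond == "reference") next
        for (comp in c("medial", "lateral")) {
          chg <- percent_change(cell[[cond]][[comp]], cell$reference[[comp]],
                                config$percent_change_floor)
          pc_rows[[length(pc_rows) + 1L]] <- data.frame(
            participant = pid, style = st, condition = cond, compartment = comp,
            phase = phase, value = as.numeric(chg))
          win <- phase >= lw[1] & phase <= lw[2]
          signed <- (cell[[cond]][[comp]] - cell$reference[[comp]]) /
            pmax(cell$reference[[comp]], config$percent_change_floor) * 100
          late_rows[[length(late_rows) + 1L]] <- data.frame(
            participant = pid, style = st, condition = cond, compartment = comp,
            signed_change = mean(signed[win]))
        }
      }
    }
  }
  percent_change_df <- do.call(rbind, pc_rows)
  peaks <- do.call(rbind, peak_rows)
  late_stance <- do.call(rbind, late_rows)

  # PP difference: modified vs normal gait under the same condition
  if ("normal" %in% config$styles) {
    for (pid in names(summaries)) {
      for (st in setdiff(config$styles, "normal")) {
        for (cond in config$strength_groups) {
          for (comp in c("medial", "lateral")) {
            sel <- function(sty) {
              r <- percent_change_df[percent_change_df$participant == pid &
                                       percent_change_df$style == sty &
                                       percent_change_df$condition == cond &
                                       percent_change_df$compartment == comp, ]
              r[order(r$phase), "value"]
            }
            vm <- sel(st); vn <- sel("normal")
            if (length(vm) == 0 || length(vn) == 0) next
            phase <- sort(unique(percent_change_df$phase))
            pp_rows[[length(pp_rows) + 1L]] <- data.frame(
              participant = pid, style = st, condition = cond, compartment = comp,
              phase = phase, value = pp_difference(vm, vn))
          }
        }
      }
    }
  }
  pp_df <- if (length(pp_rows)) do.call(rbind, pp_rows) else
    data.frame(participant = character(), style = character(),
               condition = character(), compartment = character(),
               phase = numeric(), value = numeric())

  # tests: paired t on peak stress (reduced vs reference), per style,
  # condition and compartment; RM-ANOVA with Bonferroni post hocs on speeds
  pt_rows <- list()
  for (st in config$styles) {
    for (cond in config$strength_groups) {
      for (comp in c("medial", "lateral")) {
        x <- peaks[peaks$style == st & peaks$condition == cond &
                     peaks$compartment == comp, ]
        y <- peaks[peaks$style == st & peaks$condition == "reference" &
                     peaks$compartment == comp, ]
        key <- intersect(x$participant, y$participant)
        if (length(key) < 2) next
        tt <- paired_t(x$peak[match(key, x$participant)],
                       y$peak[match(key, y$participant)])
        pt_rows[[length(pt_rows) + 1L]] <- data.frame(
          style = st, condition = cond, compartment = comp,
          t = tt$t, df = tt$df, p = tt$p, mean_difference = tt$mean_difference,
          significant = tt$p < 0.05)
      }
    }
  }
  speed_by <- tapply(speeds$speed, list(speeds$participant, speeds$style), mean)
  speed_by <- speed_by[, config$styles, drop = FALSE]
  speed_anova <- if (ncol(speed_by) >= 2 && nrow(speed_by) >= 2)
    rm_anova_bonferroni(speed_by) else NULL

  # cohort-level mean +/- 95% CI of the PP curves per (style, condition,
  # compartment)
  cohort_pp <- list()
  if (nrow(pp_df) > 0 && config$n_participants >= 2) {
    for (st in setdiff(config$styles, "normal")) {
      for (cond in config$strength_groups) {
        for (comp in c("medial", "lateral")) {
          sub <- pp_df[pp_df$style == st & pp_df$condition == cond &
                         pp_df$compartment == comp, ]
          if (nrow(sub) == 0) next
          mat <- do.call(rbind, lapply(split(sub$value, sub$participant), I))
          cohort_pp[[paste(st, cond, comp, sep = ".")]] <-
            c(list(style = st, condition = cond, compartment = comp),
              cohort_aggregate(mat))
        }
      }
    }
  }

  structure(
    list(stress = stress, percent_change = percent_change_df,
         pp_difference = pp_df, peaks = peaks, speeds = speeds,
         late_stance = late_stance,
         tests = list(peak_paired_t = do.call(rbind, pt_rows),
                      speed_anova = speed_anova),
         cohort = cohort_pp,
         foundation_modulus = modulus,
         manifest = list(
           config_hash = config_hash(config),
           master_seed = config$master_seed,
           participant_seeds = vapply(cohort$participants, `[[`, 0L, "seed"),
           n_cells = length(summaries) * length(config$styles) * length(conditions),
           failures = failures),
         config = config),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "<study_result>  %d participants x %d styles x %d conditions; %d failures\n",
    length(unique(x$stress$participant)), length(unique(x$stress$style)),
    length(unique(x$stress$condition)), length(x$manifest$failures)))
  cat(sprintf("  foundation modulus %.2f MPa; master seed %d\n",
              x$foundation_modulus / 1e6, x$manifest$master_seed))
  invisible(x)
}
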