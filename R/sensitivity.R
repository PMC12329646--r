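# Sensitivity statistics of cartilage stress to muscle-strength reduction:
# the percent change of stress between a reduced-strength and the reference
# condition,
#   %Change = | (sigma_reduced - sigma_ref) / sigma_ref | * 100,
# its difference between a modified gait and normal gait in percentage
# points,
#   PP_Difference = %Change_modified - %Change_normal
# (negative = the modified gait is less sensitive to that strength
# reduction), cohort mean +/- 95% CI curves, and the statistical tests:
# paired t on peak stresses and one-way repeated-measures ANOVA with
# Bonferroni-corrected post hocs on walking speeds.

#' Percent change of a stress series relative to the reference condition
#'
#' Elementwise `|sigma_red - sigma_ref| / sigma_ref * 100`. Samples where
#' the reference stress falls below `floor` (default 0.01 MPa) are masked
#' (`NA`) rather than divided.
#'
#' @param sigma_reduced stress series under reduced strength, MPa
#' @param sigma_ref stress series under reference strength, MPa
#' @param floor minimum reference stress for a valid ratio, MPa
#' @return percent series, `NA` at masked samples
#' @export
percent_change <- function(sigma_reduced, sigma_ref, floor = 0.01) {
  if (length(sigma_reduced) != length(sigma_ref)) {
    stop_gaitsens("gaitsens_invalid_input", "series must share a grid")
  }
  out <- abs(sigma_reduced - sigma_ref) / sigma_ref * 100
  out[sigma_ref <= floor] <- NA_real_
  if (all(is.na(out))) {
    attr(out, "empty") <- TRUE
  }
  out
}

#' Percentage-point difference between gait-modification change curves
#'
#' `PP = change_modified - change_normal`, both already non-negative percent
#' series from [percent_change()] under the same strength condition.
#' Negative values mean the modified gait's stress is less sensitive to the
#' strength reduction than normal gait.
#'
#' @param change_modified percent series in the modified gait
#' @param change_normal percent series in normal gait
#' @return percentage-point series
#' @export
pp_difference <- function(change_modified, change_normal) {
  if (length(change_modified) != length(change_normal)) {
    stop_gaitsens("gaitsens_invalid_input", "series must share a grid")
  }
  change_modified - change_normal
}

#' Cohort mean and t-based 95% confidence interval curves
#'
#' @param curves matrix (participants x samples) or list of equal-length
#'   numeric vectors
#' @return list with `mean`, `lower`, `upper`, `n`
#' @export
cohort_aggregate <- function(curves) {
  if (is.list(curves)) curves <- do.call(rbind, curves)
  n <- nrow(curves)
  if (is.null(n) || n < 2) {
    stop_gaitsens("gaitsens_insufficient_data", "need >= 2 participants")
  }
  m <- colMeans(curves)
  se <- apply(curves, 2, stats::sd) / sqrt(n)
  tq <- stats::qt(0.975, n - 1)
  list(mean = m, lower = m - tq * se, upper = m + tq * se, n = n)
}

#' Paired t test on per-participant scalars
#'
#' Classical two-sided paired t (via [stats::t.test()]); zero-variance
#' differences with a nonzero mean are flagged as an infinite-t result
#' instead of erroring.
#'
#' @param x,y equal-length paired vectors (one value per participant)
#' @return list with `t`, `df`, `p`, `mean_difference`, `infinite`
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_gaitsens("gaitsens_invalid_input", "need equal-length paired vectors, n >= 2")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = length(d) - 1, p = 1, mean_difference = 0,
                  infinite = FALSE))
    }
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                mean_difference = mean(d), infinite = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_difference = unname(ht$estimate), infinite = FALSE)
}

#' One-way repeated-measures ANOVA with Bonferroni post hocs
#'
#' Condition is the within-participant factor; the F statistic is the
#' classical participant-blocked one-way RM-ANOVA F (via [stats::aov()]).
#' Pairwise paired t tests are Bonferroni-corrected by multiplying each raw
#' p by the number of comparisons (capped at 1). No sphericity correction
#' is applied.
#'
#' @param values matrix (participants x conditions), complete
#' @return list with `F`, `df`, `p`, `pairwise` (data frame of raw and
#'   adjusted p per condition pair)
#' @export
rm_anova_bonferroni <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) {
    stop_gaitsens("gaitsens_invalid_input", "missing cells in the design matrix")
  }
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) {
    stop_gaitsens("gaitsens_invalid_input", "need >= 2 participants and >= 2 conditions")
  }
  if (is.null(colnames(values))) colnames(values) <- paste0("c", seq_len(k))
  if (all(values == values[, 1])) { # no condition effect at all: F = 0 exactly
    pairs <- utils::combn(colnames(values), 2)
    pw <- data.frame(a = pairs[1, ], b = pairs[2, ],
                     p_raw = rep(1, ncol(pairs)), p_adjusted = rep(1, ncol(pairs)))
    return(list(F = 0, df = c(k - 1, (n - 1) * (k - 1)), p = 1, pairwise = pw,
                alpha = 0.05, sphericity_correction = "none"))
  }
  df <- data.frame(
    y = as.vector(values),
    participant = factor(rep(seq_len(n), k)),
    condition = factor(rep(colnames(values), each = n),
                       levels = colnames(values))
  )
  fit <- stats::aov(y ~ condition + Error(participant / condition), data = df)
  tab <- summary(fit)[["Error: participant:condition"]][[1]]
  Fv <- tab["condition", "F value"]
  pv <- tab["condition", "Pr(>F)"]
  dfs <- tab[, "Df"]
  pairs <- utils::combn(colnames(values), 2)
  n_comp <- ncol(pairs)
  pw <- data.frame(
    a = pairs[1, ], b = pairs[2, ],
    p_raw = apply(pairs, 2, function(pr) paired_t(values[, pr[1]], values[, pr[2]])$p)
  )
  pw$p_adjusted <- pmin(pw$p_raw * n_comp, 1)
  list(F = unname(Fv), df = unname(dfs), p = unname(pv), pairwise = pw,
       alpha = 0.05, sphericity_correction = "none")
}

#' Per-style walking-speed summary table
#'
#' Maximum, minimum and mean +/- SD of the generated self-selected walking
#' speeds per gait style, one row per style.
#'
#' @param speeds data frame with columns `style` and `speed` (m/s), as in a
#'   `study_result`
#' @return data frame with columns `style`, `max_speed`, `min_speed`,
#'   `mean_speed`, `sd_speed`
#' @export
speed_summary <- function(speeds) {
  styles <- unique(speeds$style)
  do.call(rbind, lapply(styles, function(st) {
    v <- speeds$speed[speeds$style == st]
    data.frame(style = st, max_speed = max(v), min_speed = min(v),
               mean_speed = mean(v), sd_speed = stats::sd(v))
  }))
}
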