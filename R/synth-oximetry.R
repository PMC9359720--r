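#' @include synth-growth.R
NULL

#' Configuration of synthetic longitudinal oximetry trajectories
#'
#' Parametrizes piecewise-linear apparent-oxygenation (SO2) and normalized
#' total-hemoglobin (THb) trajectories: every group shares a common slope up
#' to the knot day, after which each analysis group (control, nonresponder,
#' responder) follows its own slope, with Gaussian mouse and tumor random
#' intercepts and residual noise. Simulated SO2 values are clamped to
#' `[0, 1]`.
#'
#' Defaults emulate a study in which control oxygenation rises steadily from
#' about 0.45 at enrollment to about 0.58 at week 6, nonresponders parallel
#' the controls, and responders diverge downward after week 3 toward about
#' 0.31 — while normalized THb rises slightly in controls, falls in
#' nonresponders and stays flat in responders.
#'
#' @param knot_day day of the slope change (default 21, i.e. 3 weeks).
#' @param so2_baseline_mean,so2_baseline_sd mean and SD of the SO2 intercept.
#' @param so2_pre_slope common pre-knot SO2 slope (per day).
#' @param so2_post_slopes named numeric (control, nonresponder, responder)
#'   post-knot SO2 slopes (per day).
#' @param thb_baseline_mean,thb_baseline_sd,thb_pre_slope,thb_post_slopes
#'   analogous parameters for normalized THb (unitless, not clamped).
#' @param sd_mouse,sd_tumor,sd_residual random-intercept and residual SDs
#'   (shared by the SO2 and THb responses).
#' @param seed integer seed.
#' @return A list of class `OximetrySimConfig`.
#' @seealso [simulateOximetryTrajectories()]
#' @export
oximetrySimConfig <- function(knot_day = 21,
                              so2_baseline_mean = 0.45, so2_baseline_sd = 0.03,
                              so2_pre_slope = 0.003,
                              so2_post_slopes = c(control = 0.003,
                                                  nonresponder = 0.003,
                                                  responder = -0.010),
                              thb_baseline_mean = 1.0, thb_baseline_sd = 0.1,
                              thb_pre_slope = 0.004,
                              thb_post_slopes = c(control = 0.004,
                                                  nonresponder = -0.008,
                                                  responder = 0.000),
                              sd_mouse = 0.03, sd_tumor = 0.02,
                              sd_residual = 0.03, seed = 1L) {
  .checkPositiveScalar(knot_day, "knot_day")
  if (so2_baseline_mean < 0 || so2_baseline_mean > 1)
    stop("invalid 'so2_baseline_mean': must lie in [0, 1]")
  for (f in c("so2_baseline_sd", "thb_baseline_sd", "sd_mouse", "sd_tumor",
              "sd_residual"))
    .checkPositiveScalar(get(f), f, allow_zero = TRUE)
  if (!all(.GROUPS %in% names(so2_post_slopes)) ||
      !all(.GROUPS %in% names(thb_post_slopes)))
    stop("post-knot slopes must be named vectors covering ",
         paste(.GROUPS, collapse = ", "))
  structure(list(knot_day = knot_day,
                 so2_baseline_mean = so2_baseline_mean,
                 so2_baseline_sd = so2_baseline_sd,
                 so2_pre_slope = so2_pre_slope,
                 so2_post_slopes = so2_post_slopes[.GROUPS],
                 thb_baseline_mean = thb_baseline_mean,
                 thb_baseline_sd = thb_baseline_sd,
                 thb_pre_slope = thb_pre_slope,
                 thb_post_slopes = thb_post_slopes[.GROUPS],
                 sd_mouse = sd_mouse, sd_tumor = sd_tumor,
                 sd_residual = sd_residual, seed = as.integer(seed)),
            class = "OximetrySimConfig")
}

# Piecewise mean: baseline + pre * min(t, knot) + post * max(0, t - knot).
.piecewiseMean <- function(baseline, pre, post, day, knot) {
  baseline + pre * pmin(day, knot) + post * pmax(0, day - knot)
}

#' Simulate longitudinal oximetry trajectories for a cohort
#'
#' Generates per-tumor per-day SO2 and normalized-THb records following the
#' piecewise-linear mean structure of an [oximetrySimConfig()] — a common
#' slope for every group before the knot and group-specific slopes afterwards
#' — on the mouse/tumor/day grid of an existing growth cohort.
#'
#' @param config an `OximetrySimConfig`.
#' @param cohort data.frame from [simulateGrowthCohort()] (or any table with
#'   mouse_id, tumor_id, true_group, day).
#' @param seed optional integer overriding `config$seed`.
#' @return data.frame with columns mouse_id, tumor_id, group, day, so2
#'   (clamped to `[0, 1]`), thb_normalized.
#' @export
simulateOximetryTrajectories <- function(config, cohort, seed = NULL) {
  if (!inherits(config, "OximetrySimConfig"))
    stop("'config' must come from oximetrySimConfig()")
  need <- c("mouse_id", "tumor_id", "true_group", "day")
  if (!all(need %in% names(cohort)))
    stop("cohort must provide columns ", paste(need, collapse = ", "))
  if (config$knot_day < min(cohort$day) || config$knot_day > max(cohort$day))
    stop("knot_day ", config$knot_day, " lies outside the observed day range [",
         min(cohort$day), ", ", max(cohort$day), "]")
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  obs <- unique(cohort[c("mouse_id", "tumor_id", "true_group", "day")])
  obs <- obs[order(obs$mouse_id, obs$tumor_id, obs$day), , drop = FALSE]
  mice <- sort(unique(obs$mouse_id))
  tumors <- sort(unique(obs$tumor_id))
  m_re <- setNames(rnorm(length(mice), 0, config$sd_mouse), mice)
  t_re <- setNames(rnorm(length(tumors), 0, config$sd_tumor), tumors)
  m_base_so2 <- setNames(rnorm(length(mice), 0, config$so2_baseline_sd), mice)
  m_base_thb <- setNames(rnorm(length(mice), 0, config$thb_baseline_sd), mice)
  g <- obs$true_group
  so2_mu <- .piecewiseMean(config$so2_baseline_mean, config$so2_pre_slope,
                           config$so2_post_slopes[g], obs$day, config$knot_day)
  thb_mu <- .piecewiseMean(config$thb_baseline_mean, config$thb_pre_slope,
                           config$thb_post_slopes[g], obs$day, config$knot_day)
  n <- nrow(obs)
  so2 <- so2_mu + m_base_so2[obs$mouse_id] + m_re[obs$mouse_id] +
    t_re[obs$tumor_id] + rnorm(n, 0, config$sd_residual)
  thb <- thb_mu + m_base_thb[obs$mouse_id] + m_re[obs$mouse_id] +
    t_re[obs$tumor_id] + rnorm(n, 0, config$sd_residual)
  data.frame(mouse_id = obs$mouse_id, tumor_id = obs$tumor_id,
             group = g, day = obs$day,
             so2 = pmin(1, pmax(0, so2)), thb_normalized = thb,
             row.names = NULL, stringsAsFactors = FALSE)
}
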