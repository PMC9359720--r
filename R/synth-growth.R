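#' @include AllClasses.R
NULL

.GROUPS <- c("control", "nonresponder", "responder")

.checkPositiveScalar <- function(x, field, allow_zero = FALSE) {
  if (length(x) != 1L || !is.finite(x) || (if (allow_zero) x < 0 else x <= 0))
    stop("invalid '", field, "': must be a single ",
         if (allow_zero) "non-negative" else "positive", " number")
  invisible(x)
}

#' Configuration of the synthetic tumor-growth cohort
#'
#' Parametrizes a two-arm xenograft cohort whose tumor volumes follow a
#' power-law (cube-root-linear) growth model with hierarchical Gaussian random
#' effects: cube-root volume = (intercept + mouse + tumor intercept effects) +
#' (class slope + mouse + tumor slope effects) * day + residual; volumes are
#' the cube of that value, floored at zero. Treated mice split into a
#' responder subgroup (near-flat growth) and nonresponders (control-like
#' growth).
#'
#' Defaults mirror a typical bevacizumab xenograft study arm: 8 control and 11
#' treated mice with 2 tumors each, weekly calliper volumes over 6 weeks from
#' enrollment at 500 mm^3, control/nonresponder cube-root slope 0.08 mm/day
#' and responder slope 0.01 mm/day, responder fraction 3/11.
#'
#' @param n_control,n_treated number of mice per arm.
#' @param tumors_per_mouse tumors implanted per mouse (default 2).
#' @param days observation days from enrollment (non-negative, strictly
#'   increasing); default weekly over 6 weeks.
#' @param intercept_mean mean cube-root volume at enrollment (mm).
#' @param slope_control,slope_nonresponder,slope_responder mean cube-root
#'   growth rates (mm/day) per class.
#' @param sd_mouse_intercept,sd_tumor_intercept,sd_tumor_slope,sd_residual
#'   Gaussian random-effect and residual SDs on the cube-root scale.
#' @param sd_mouse_slope mouse-level slope SD; either a single value shared by
#'   all classes or a named vector with entries "control", "nonresponder",
#'   "responder".
#' @param responder_fraction proportion of treated mice that are responders;
#'   the responder count is `round(responder_fraction * n_treated)` so class
#'   sizes are deterministic.
#' @param seed integer seed used by [simulateGrowthCohort()].
#' @return A list of class `GrowthSimConfig`.
#' @seealso [simulateGrowthCohort()], [boundaryStressConfig()]
#' @export
growthSimConfig <- function(n_control = 8, n_treated = 11, tumors_per_mouse = 2,
                            days = seq(0, 42, by = 7),
                            intercept_mean = 500^(1 / 3),
                            slope_control = 0.08,
                            slope_nonresponder = 0.08,
                            slope_responder = 0.01,
                            sd_mouse_intercept = 0.5,
                            sd_tumor_intercept = 0.3,
                            sd_mouse_slope = 0.015,
                            sd_tumor_slope = 0.005,
                            sd_residual = 0.3,
                            responder_fraction = 3 / 11,
                            seed = 1L) {
  if (n_control < 0 || n_treated < 1)
    stop("invalid 'n_treated'/'n_control': need at least one treated mouse")
  if (tumors_per_mouse < 1) stop("invalid 'tumors_per_mouse': must be >= 1")
  if (any(days < 0) || (length(days) > 1 && any(diff(days) <= 0)))
    stop("invalid 'days': must be non-negative and strictly increasing")
  for (f in c("sd_mouse_intercept", "sd_tumor_intercept", "sd_tumor_slope",
              "sd_residual"))
    .checkPositiveScalar(get(f), f, allow_zero = TRUE)
  if (any(sd_mouse_slope < 0) || !all(is.finite(sd_mouse_slope)))
    stop("invalid 'sd_mouse_slope': SDs must be non-negative")
  if (length(sd_mouse_slope) == 1L) {
    sd_mouse_slope <- setNames(rep(sd_mouse_slope, 3L), .GROUPS)
  } else if (!all(.GROUPS %in% names(sd_mouse_slope))) {
    stop("invalid 'sd_mouse_slope': named vector must cover ",
         paste(.GROUPS, collapse = ", "))
  }
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("invalid 'responder_fraction': must lie in [0, 1]")
  structure(list(
    n_control = as.integer(n_control), n_treated = as.integer(n_treated),
    tumors_per_mouse = as.integer(tumors_per_mouse), days = as.numeric(days),
    intercept_mean = intercept_mean,
    slopes = c(control = slope_control, nonresponder = slope_nonresponder,
               responder = slope_responder),
    sd_mouse_intercept = sd_mouse_intercept,
    sd_tumor_intercept = sd_tumor_intercept,
    sd_mouse_slope = sd_mouse_slope[.GROUPS],
    sd_tumor_slope = sd_tumor_slope, sd_residual = sd_residual,
    responder_fraction = responder_fraction, seed = as.integer(seed)),
    class = "GrowthSimConfig")
}

#' Boundary-stress growth configuration
#'
#' A growth configuration in which the average growth-rate difference between
#' responder and nonresponder classes is small, stressing the classifiers
#' near the decision boundary: responder mouse slopes ~ Normal(0.03, 0.01),
#' nonresponder/control slopes ~ Normal(0.08, 0.02) on the cube-root scale,
#' residual SD 0.05, weekly observations over 6 weeks, 6 treated (3 responder)
#' and 8 control mice with 2 tumors each.
#'
#' @param seed integer seed.
#' @return A `GrowthSimConfig`.
#' @seealso [evaluateClassifier()]
#' @export
boundaryStressConfig <- function(seed = 1L) {
  growthSimConfig(
    n_control = 8, n_treated = 6, tumors_per_mouse = 2,
    days = seq(0, 42, by = 7),
    slope_control = 0.08, slope_nonresponder = 0.08, slope_responder = 0.03,
    sd_mouse_intercept = 0.3, sd_tumor_intercept = 0.2,
    sd_mouse_slope = c(control = 0.02, nonresponder = 0.02, responder = 0.01),
    sd_tumor_slope = 0, sd_residual = 0.05,
    responder_fraction = 0.5, seed = seed)
}

#' Simulate a longitudinal tumor-volume cohort
#'
#' Draws a cohort from the cube-root-linear hierarchical growth model of a
#' [growthSimConfig()], returning one row per tumor per observation day with
#' the ground-truth class labels alongside.
#'
#' @param config a `GrowthSimConfig`.
#' @param seed optional integer overriding `config$seed`.
#' @return data.frame with columns mouse_id, tumor_id, arm ("control"/
#'   "treated"), true_group ("control"/"nonresponder"/"responder"), day,
#'   volume_mm3.
#' @examples
#' cohort <- simulateGrowthCohort(growthSimConfig(n_control = 2, n_treated = 2))
#' head(cohort)
#' @export
simulateGrowthCohort <- function(config, seed = NULL) {
  if (!inherits(config, "GrowthSimConfig"))
    stop("'config' must come from growthSimConfig()")
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  n_resp <- round(config$responder_fraction * config$n_treated)
  n_mice <- config$n_control + config$n_treated
  mouse_id <- sprintf("M%02d", seq_len(n_mice))
  arm <- rep(c("control", "treated"), c(config$n_control, config$n_treated))
  group <- ifelse(arm == "control", "control", "nonresponder")
  if (n_resp > 0) {
    resp_idx <- config$n_control +
      sample.int(config$n_treated, n_resp, replace = FALSE)
    group[resp_idx] <- "responder"
  }
  days <- config$days
  rows <- vector("list", n_mice)
  for (m in seq_len(n_mice)) {
    g <- group[m]
    m_int <- rnorm(1, 0, config$sd_mouse_intercept)
    m_slp <- rnorm(1, 0, config$sd_mouse_slope[[g]])
    tum <- vector("list", config$tumors_per_mouse)
    for (t in seq_len(config$tumors_per_mouse)) {
      t_int <- rnorm(1, 0, config$sd_tumor_intercept)
      t_slp <- rnorm(1, 0, config$sd_tumor_slope)
      y <- config$intercept_mean + m_int + t_int +
        (config$slopes[[g]] + m_slp + t_slp) * days +
        rnorm(length(days), 0, config$sd_residual)
      tum[[t]] <- data.frame(
        mouse_id = mouse_id[m],
        tumor_id = sprintf("%s_T%d", mouse_id[m], t),
        arm = arm[m], true_group = g, day = days,
        volume_mm3 = pmax(y, 0)^3,
        stringsAsFactors = FALSE)
    }
    rows[[m]] <- do.call(rbind, tum)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ground-truth labels of a simulated cohort
#'
#' @param cohort data.frame from [simulateGrowthCohort()].
#' @param level "mouse" or "tumor".
#' @return data.frame (unit_id, arm, true_group), one row per unit.
#' @export
cohortTruth <- function(cohort, level = c("mouse", "tumor")) {
  level <- match.arg(level)
  key <- if (level == "mouse") cohort$mouse_id else cohort$tumor_id
  out <- unique(data.frame(unit_id = key, arm = cohort$arm,
                           true_group = cohort$true_group,
                           stringsAsFactors = FALSE))
  out[order(out$unit_id), , drop = FALSE]
}
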