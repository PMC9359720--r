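#' @include synth-growth.R
NULL

#' Cube-root transform of tumor volumes
#'
#' Tumor growth analyses run on the cube-root scale, on which power-law
#' growth is linear in time and the slope has units of length per day.
#'
#' @param volume numeric vector of volumes (mm^3), non-negative.
#' @return numeric vector of cube roots (mm).
#' @examples
#' cubeRoot(1000)
#' @export
cubeRoot <- function(volume) {
  if (any(!is.finite(volume))) stop("volumes must be finite")
  if (any(volume < 0)) stop("volumes must be non-negative")
  volume^(1 / 3)
}

#' Ordinary least-squares growth slope of one series
#'
#' Fits a straight line to cube-root volume versus day for a single unit
#' (one tumor, or one mouse's pooled tumors).
#'
#' @param day numeric observation days.
#' @param volume numeric volumes in mm^3 (same length as `day`).
#' @return list with slope (cube-root mm/day), intercept (mm), r_squared,
#'   n_obs.
#' @examples
#' fitGrowthSlope(c(0, 7, 14), (1 + 0.1 * c(0, 7, 14))^3)$slope
#' @export
fitGrowthSlope <- function(day, volume) {
  if (length(day) != length(volume)) stop("day and volume lengths differ")
  if (length(day) < 2L) stop("at least 2 observations are required")
  if (length(unique(day)) < 2L) stop("all observation days are identical")
  y <- cubeRoot(volume)
  fit <- lm(y ~ day)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n_obs = length(day))
}

#' Per-unit growth slopes of a cohort
#'
#' Computes the OLS cube-root growth slope of every mouse or tumor in a
#' longitudinal volume table. At the mouse level each mouse's tumors are
#' pooled into a single fit.
#'
#' @param cohort data.frame with mouse_id, tumor_id, day, volume_mm3 and
#'   optionally arm.
#' @param level "mouse" or "tumor".
#' @return data.frame (unit_id, arm, slope, intercept, r_squared, n_obs),
#'   ordered by unit_id.
#' @export
fitGrowthSlopes <- function(cohort, level = c("mouse", "tumor")) {
  level <- match.arg(level)
  key <- if (level == "mouse") cohort$mouse_id else cohort$tumor_id
  pieces <- split(cohort, key)
  out <- do.call(rbind, lapply(names(pieces), function(id) {
    s <- pieces[[id]]
    f <- fitGrowthSlope(s$day, s$volume_mm3)
    data.frame(unit_id = id,
               arm = if ("arm" %in% names(s)) s$arm[1L] else NA_character_,
               slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, n_obs = f$n_obs,
               stringsAsFactors = FALSE)
  }))
  out[order(out$unit_id), , drop = FALSE]
}

#' Threshold responder classification
#'
#' Labels a unit "responder" when its cube-root growth slope is strictly
#' below the threshold (default 0.05 mm/day), "nonresponder" otherwise — a
#' slope exactly at the threshold is a nonresponder. The threshold is
#' expressed on the cube-root mm/day scale: re-expressing volumes in other
#' units rescales slopes by the cube root of the volume factor, so the
#' threshold must be rescaled accordingly.
#'
#' @param slope numeric vector of cube-root growth slopes.
#' @param threshold classification cut (default 0.05).
#' @return character vector of "responder"/"nonresponder".
#' @examples
#' thresholdClassify(c(0.0, 0.05, 0.12))
#' @export
thresholdClassify <- function(slope, threshold = 0.05) {
  if (any(!is.finite(slope))) stop("slopes must be finite")
  ifelse(slope < threshold, "responder", "nonresponder")
}

#' Significance-based responder classification against controls
#'
#' Labels a treated unit "responder" when its growth slope falls below the
#' lower one-sided `1 - alpha` confidence bound of the control-group mean
#' slope, `mean(ctrl) - t_{1-alpha, n-1} * sd(ctrl) / sqrt(n)`. Because the
#' bound tightens toward the control mean as the control sample grows, the
#' probability of flagging control-like growth as response increases with
#' control sample size — the misclassification behavior this rule is used to
#' characterize.
#'
#' @param slope numeric vector of treated-unit slopes.
#' @param control_slopes numeric vector of control-unit slopes (>= 2).
#' @param alpha one-sided level of the confidence bound (default 0.05).
#' @return character vector of "responder"/"nonresponder".
#' @seealso [thresholdClassify()], [evaluateClassifier()]
#' @export
significanceClassify <- function(slope, control_slopes, alpha = 0.05) {
  n <- length(control_slopes)
  if (n < 2L) stop("at least 2 control slopes are required")
  bound <- mean(control_slopes) -
    qt(1 - alpha, n - 1L) * sd(control_slopes) / sqrt(n)
  ifelse(slope < bound, "responder", "nonresponder")
}

#' Compare growth-linearizing transforms
#'
#' Fits per-series straight lines to cube-root volume versus day (power-law
#' growth) and to log volume versus day (exponential growth) and reports
#' which transform linearizes the cohort better, by mean per-series R
#' squared. Series containing zero volumes are excluded from the log fit
#' (their count is reported).
#'
#' @param cohort data.frame with tumor_id, day, volume_mm3; series need at
#'   least 3 observations.
#' @return list: per_series data.frame (unit_id, r2_cuberoot, r2_log),
#'   mean_r2_cuberoot, mean_r2_log, winner ("cuberoot" or "log"),
#'   n_log_excluded.
#' @export
compareGrowthTransforms <- function(cohort) {
  pieces <- split(cohort, cohort$tumor_id)
  if (any(vapply(pieces, nrow, integer(1)) < 3L))
    stop("every series needs at least 3 observations")
  r2 <- function(x, y) {
    fit <- lm(y ~ x)
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) return(1)
    1 - sum(residuals(fit)^2) / ss_tot
  }
  n_log_excluded <- 0L
  per <- do.call(rbind, lapply(names(pieces), function(id) {
    s <- pieces[[id]]
    r2c <- r2(s$day, cubeRoot(s$volume_mm3))
    r2l <- if (any(s$volume_mm3 <= 0)) {
      n_log_excluded <<- n_log_excluded + 1L
      NA_real_
    } else r2(s$day, log(s$volume_mm3))
    data.frame(unit_id = id, r2_cuberoot = r2c, r2_log = r2l,
               stringsAsFactors = FALSE)
  }))
  if (n_log_excluded > 0L)
    warning(n_log_excluded, " series with zero volumes excluded from the log fit")
  m_c <- mean(per$r2_cuberoot)
  m_l <- mean(per$r2_log, na.rm = TRUE)
  list(per_series = per, mean_r2_cuberoot = m_c, mean_r2_log = m_l,
       winner = if (m_c >= m_l || !is.finite(m_l)) "cuberoot" else "log",
       n_log_excluded = n_log_excluded)
}
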