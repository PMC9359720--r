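# Shared fixtures and independent oracle helpers (built in code, no files).

# Quiet ML lmer fit of the joint two-class growth model for a given responder
# unit set -- the independent oracle for EM allocation (exhaustive search).
oracle_joint_deviance <- function(cohort, resp_units, level = "mouse") {
  df <- data.frame(mouse_id = cohort$mouse_id, tumor_id = cohort$tumor_id,
                   day = cohort$day, y = cohort$volume_mm3^(1 / 3))
  unit <- if (level == "mouse") df$mouse_id else df$tumor_id
  df$resp <- as.numeric(unit %in% resp_units)
  df$resp_day <- df$resp * df$day
  form <- if (length(unique(df$resp)) > 1L)
    y ~ day + resp + resp_day + (day | mouse_id) + (1 | tumor_id)
  else
    y ~ day + (day | mouse_id) + (1 | tumor_id)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, df, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore",
                                           check.conv.grad = "ignore",
                                           check.conv.hess = "ignore"))))
  as.numeric(-2 * logLik(fit))
}

# Exhaustive minimum joint deviance over all 2^k responder allocations.
oracle_exhaustive_allocation <- function(cohort, level = "mouse") {
  units <- sort(unique(
    (if (level == "mouse") cohort$mouse_id else cohort$tumor_id)[
      cohort$arm == "treated"]))
  k <- length(units)
  best <- Inf; best_resp <- character(0)
  for (code in 0:(2^k - 1)) {
    resp <- units[as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)))]
    d <- oracle_joint_deviance(cohort, resp, level)
    if (d < best - 1e-9) { best <- d; best_resp <- resp }
  }
  list(deviance = best, responders = best_resp)
}

# Small, well-separated allocation fixture: 6 treated mice, 3 near-flat.
separated_cohort <- function(seed = 9) {
  simulateGrowthCohort(growthSimConfig(
    n_control = 4, n_treated = 6, tumors_per_mouse = 2,
    slope_control = 0.15, slope_nonresponder = 0.15, slope_responder = 0.01,
    sd_mouse_intercept = 0.3, sd_tumor_intercept = 0.2,
    sd_mouse_slope = 0.01, sd_tumor_slope = 0, sd_residual = 0.05,
    responder_fraction = 0.5, seed = seed))
}

# Null-growth configuration: treated slopes drawn from the control
# distribution (no responder subgroup simulated).
null_growth_config <- function() {
  cfg <- boundaryStressConfig()
  cfg$slopes["responder"] <- cfg$slopes["nonresponder"]
  cfg$sd_mouse_slope["responder"] <- cfg$sd_mouse_slope["nonresponder"]
  cfg
}

# Two-group log-rank statistic computed by the hypergeometric hand formula.
oracle_logrank_chisq <- function(time, event, group) {
  group <- as.character(group)
  g1 <- unique(group)[1L]
  obs <- 0; expe <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & group == g1)
    obs <- obs + d1
    expe <- expe + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (obs - expe)^2 / v
}
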