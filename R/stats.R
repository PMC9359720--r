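#' @include synth-growth.R
NULL

#' Variance-aware two-sample t test
#'
#' Two-sided t test following the endpoint-comparison convention: unpaired
#' comparisons use a Student t test unless a two-sided F-ratio pretest at
#' `alpha_var` finds unequal variances, in which case a Welch t test is used;
#' paired comparisons bypass the pretest. Two groups that are constant and
#' equal give statistic 0 and p = 1 by convention.
#'
#' @param x,y numeric samples (>= 2 values each; equal lengths and matched
#'   order when `paired`).
#' @param paired paired comparison of the same tumors before/after treatment.
#' @param alpha_var level of the variance pretest (default 0.05).
#' @return list of class `TwoSampleResult`: statistic, df, p_value, method
#'   ("student", "welch" or "paired"), group means/SDs, variance_pretest_p.
#' @examples
#' ttestAuto(c(1, 2, 3), c(4, 5, 6))$p_value
#' @export
ttestAuto <- function(x, y, paired = FALSE, alpha_var = 0.05) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  if (paired && length(x) != length(y))
    stop("paired test requires equal-length, matched samples")
  out <- list(mean_x = mean(x), mean_y = mean(y),
              sd_x = sd(x), sd_y = sd(y), variance_pretest_p = NA_real_)
  if (paired) {
    d <- x - y
    if (all(d == 0))
      return(c(list(statistic = 0, df = length(d) - 1, p_value = 1,
                    method = "paired"), out))
    tt <- t.test(x, y, paired = TRUE)
    return(structure(c(list(statistic = unname(tt$statistic),
                            df = unname(tt$parameter),
                            p_value = tt$p.value, method = "paired"), out),
                     class = "TwoSampleResult"))
  }
  if (out$sd_x == 0 && out$sd_y == 0) {
    eq <- isTRUE(all.equal(out$mean_x, out$mean_y))
    return(structure(c(list(statistic = if (eq) 0 else Inf,
                            df = length(x) + length(y) - 2,
                            p_value = if (eq) 1 else 0,
                            method = "student"), out),
                     class = "TwoSampleResult"))
  }
  pre_p <- if (out$sd_x == 0 || out$sd_y == 0) 0
           else var.test(x, y)$p.value
  out$variance_pretest_p <- pre_p
  welch <- pre_p < alpha_var
  tt <- t.test(x, y, var.equal = !welch)
  structure(c(list(statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   method = if (welch) "welch" else "student"), out),
            class = "TwoSampleResult")
}

#' Pearson correlation test
#'
#' Pearson product-moment correlation with the two-sided t-approximation
#' p-value, as used for relating imaging biomarkers to histology readouts.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list: r, p_value, n.
#' @examples
#' pearsonTest(1:10, 2 * (1:10))$r
#' @export
pearsonTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("at least 3 pairs are required")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input: correlation is undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Log-rank test with Kaplan-Meier curves
#'
#' Compares survival distributions between groups with the standard log-rank
#' statistic (observed versus hypergeometric-expected events summed over
#' distinct event times) and returns Kaplan-Meier step functions for
#' plotting.
#'
#' @param time numeric event/censoring times (days, >= 0).
#' @param event integer 0/1 event indicator.
#' @param group group labels (>= 2 groups).
#' @return list: chi_square, df, p_value, and `km`, a data.frame (group,
#'   time, n_risk, n_event, surv) of the Kaplan-Meier estimates.
#' @export
logrankTest <- function(time, event, group) {
  if (any(time < 0)) stop("times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("at least 2 groups are required")
  if (sum(event) == 0L) stop("all observations are censored")
  sd_ <- survdiff(Surv(time, event) ~ group)
  df <- length(sd_$n) - 1L
  km_fit <- survfit(Surv(time, event) ~ group)
  strata <- rep(names(km_fit$strata), km_fit$strata)
  km <- data.frame(group = sub("^group=", "", strata),
                   time = km_fit$time, n_risk = km_fit$n.risk,
                   n_event = km_fit$n.event, surv = km_fit$surv,
                   stringsAsFactors = FALSE)
  list(chi_square = unname(sd_$chisq), df = df,
       p_value = pchisq(sd_$chisq, df, lower.tail = FALSE), km = km)
}

#' Monte Carlo power for a clustered two-group comparison
#'
#' Estimates, by simulation, the power to detect a difference in group means
#' of a tumor-level biomarker when tumors are nested in mice (2 per mouse by
#' default) with a within-mouse correlation. Each replicate draws, per group,
#' mouse random effects with variance `icc * sd^2` and tumor-level noise with
#' variance `(1 - icc) * sd^2`, aggregates tumors to mouse means, and applies
#' the variance-pretest two-sample t rule ([ttestAuto()]) at level `alpha`;
#' power is the rejection fraction over `R` replicates.
#'
#' @param mean1,mean2 group means (e.g. endpoint SO2).
#' @param sd1,sd2 tumor-level SDs per group.
#' @param icc within-mouse correlation in `[0, 1)`.
#' @param n_mice mice per group, or a grid of values.
#' @param tumors_per_mouse tumors per mouse (default 2).
#' @param R Monte Carlo replicates (default 2500).
#' @param alpha test level (default 0.05).
#' @param target power target used to report the smallest adequate grid size.
#' @param seed integer seed.
#' @return list of class `PowerResult`: `grid`, a data.frame (n_mice,
#'   n_tumors, power), `smallest_adequate_n_mice` (NA if none on the grid
#'   exceeds `target`), and the effect specification.
#' @examples
#' \donttest{
#' mcPower(0.58, 0.31, 0.03, 0.07, icc = 0.3, n_mice = 6, R = 500)$grid
#' }
#' @export
mcPower <- function(mean1, mean2, sd1, sd2, icc = 0.3, n_mice = 6,
                    tumors_per_mouse = 2, R = 2500, alpha = 0.05,
                    target = 0.8, seed = 1L) {
  if (icc < 0 || icc >= 1) stop("'icc' must lie in [0, 1)")
  if (R < 1) stop("'R' must be at least 1")
  for (f in c("sd1", "sd2"))
    .checkPositiveScalar(get(f), f, allow_zero = TRUE)
  set.seed(as.integer(seed))
  one_group <- function(mu, sdev, n) {
    m_eff <- rnorm(n, 0, sqrt(icc) * sdev)
    tum <- matrix(rnorm(n * tumors_per_mouse, 0, sqrt(1 - icc) * sdev),
                  nrow = n)
    mu + m_eff + rowMeans(tum)
  }
  grid <- data.frame(n_mice = as.integer(n_mice),
                     n_tumors = as.integer(n_mice) * tumors_per_mouse,
                     power = NA_real_)
  for (k in seq_len(nrow(grid))) {
    n <- grid$n_mice[k]
    rej <- logical(R)
    for (r in seq_len(R)) {
      g1 <- one_group(mean1, sd1, n)
      g2 <- one_group(mean2, sd2, n)
      rej[r] <- ttestAuto(g1, g2)$p_value < alpha
    }
    grid$power[k] <- mean(rej)
  }
  ok <- grid$n_mice[grid$power > target]
  structure(list(grid = grid,
                 smallest_adequate_n_mice = if (length(ok)) min(ok) else NA,
                 effect = list(mean1 = mean1, mean2 = mean2, sd1 = sd1,
                               sd2 = sd2, icc = icc,
                               tumors_per_mouse = tumors_per_mouse),
                 R = R, alpha = alpha, target = target),
            class = "PowerResult")
}
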