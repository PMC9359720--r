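#' @include classify.R AllGenerics.R
NULL

.normalizeGroup <- function(group) {
  g <- tolower(as.character(group))
  bad <- setdiff(unique(g), .GROUPS)
  if (length(bad))
    stop("group column contains level(s) ", paste(bad, collapse = ", "),
         "; allowed levels are ", paste(.GROUPS, collapse = ", "))
  factor(g, levels = intersect(.GROUPS, unique(g)))
}

#' Piecewise (hinge) fixed-effect design matrix
#'
#' Builds the fixed-effect design of the piecewise longitudinal model: an
#' intercept, a single slope on `day` shared by all groups before the knot,
#' and one hinge column `max(0, day - knot)` per group carrying the
#' group-specific post-knot slope change. The implied mean trajectory is
#' continuous at the knot for every group, and all group-specific columns
#' vanish for days at or before the knot.
#'
#' @param day numeric observation days.
#' @param group group labels (control/nonresponder/responder, any case).
#' @param knot knot day (default 21, i.e. 3 weeks from enrollment).
#' @return numeric matrix with columns `(Intercept)`, `day`, and `h_<group>`
#'   for each group level present.
#' @examples
#' piecewiseDesign(c(14, 28), c("responder", "responder"), knot = 21)
#' @export
piecewiseDesign <- function(day, group, knot = 21) {
  g <- .normalizeGroup(group)
  hinge <- pmax(0, day - knot)
  X <- cbind(`(Intercept)` = rep(1, length(day)), day = day)
  for (lev in levels(g))
    X <- cbind(X, setNames(data.frame(hinge * (g == lev)), paste0("h_", lev)))
  as.matrix(X)
}

# Build the modeling frame and fixed-effect formula for fitLmm.
.lmmFrame <- function(data, outcome, piecewise, knot) {
  need <- c("mouse_id", "tumor_id", "group", "day")
  if (!all(need %in% names(data)))
    stop("data must provide columns ", paste(need, collapse = ", "))
  y <- switch(outcome,
    cube_root_volume = {
      if (!"volume_mm3" %in% names(data))
        stop("outcome 'cube_root_volume' needs a volume_mm3 column")
      cubeRoot(data$volume_mm3)
    },
    so2 = data$so2,
    thb_normalized = data$thb_normalized)
  if (is.null(y) || any(!is.finite(y)))
    stop("outcome '", outcome, "' is missing or not finite")
  g <- .normalizeGroup(data$group)
  mf <- data.frame(y = y, day = as.numeric(data$day), group = g,
                   mouse_id = factor(data$mouse_id),
                   tumor_id = factor(data$tumor_id))
  if (piecewise) {
    for (lev in levels(g))
      mf[[paste0("h_", lev)]] <- pmax(0, mf$day - knot) * (mf$group == lev)
    rhs <- paste(c("day", paste0("h_", levels(g))), collapse = " + ")
  } else {
    rhs <- if (nlevels(g) > 1L) "day * group" else "day"
  }
  list(mf = mf, rhs = rhs, groups = levels(g))
}

#' Fit a hierarchical linear mixed model for a longitudinal outcome
#'
#' Fits the longitudinal models of the pipeline: cube-root tumor volume, SO2
#' or normalized THb as outcome; day, group and their interaction (or the
#' piecewise hinge design of [piecewiseDesign()]) as fixed effects; mice and
#' tumors-within-mice as hierarchical random intercepts, optionally with a
#' mouse-level random slope. Estimation is REML by default (ML is required
#' for comparing models that differ in fixed effects). The heteroscedastic
#' variant lets the residual SD follow `sigma * (day + 1)^delta`.
#' Fixed-effect inference is Wald (normal); no denominator-degrees-of-freedom
#' correction is applied, a known small-sample caveat.
#'
#' @param data data.frame with mouse_id, tumor_id, group, day, and the
#'   outcome source column (volume_mm3, so2, or thb_normalized).
#' @param outcome one of "cube_root_volume", "so2", "thb_normalized".
#' @param piecewise use the hinge design with a slope change at `knot`.
#' @param knot knot day (default 21).
#' @param random "intercept" (mouse and tumor random intercepts) or "slope"
#'   (additionally a mouse-level random slope on day).
#' @param heteroscedastic allow the residual SD to vary with day (fitted with
#'   `nlme::lme`; random intercepts only).
#' @param method "REML" (default) or "ML".
#' @return An [LmmFit-class]. Boundary (zero) variance estimates are flagged
#'   in `spec$singular`, not an error.
#' @examples
#' cohort <- simulateGrowthCohort(growthSimConfig(n_control = 4, n_treated = 6))
#' cohort$group <- cohort$true_group
#' fitLmm(cohort, "cube_root_volume")
#' @export
fitLmm <- function(data, outcome = c("cube_root_volume", "so2", "thb_normalized"),
                   piecewise = FALSE, knot = 21,
                   random = c("intercept", "slope"),
                   heteroscedastic = FALSE, method = c("REML", "ML")) {
  outcome <- match.arg(outcome)
  random <- match.arg(random)
  method <- match.arg(method)
  fr <- .lmmFrame(data, outcome, piecewise, knot)
  mf <- fr$mf
  if (nlevels(mf$mouse_id) < 2L) stop("at least 2 mice are required")
  if (heteroscedastic) {
    if (random == "slope")
      stop("the heteroscedastic variant supports random intercepts only")
    fit <- tryCatch(
      lme(fixed = formula(paste("y ~", fr$rhs)),
          random = ~ 1 | mouse_id / tumor_id,
          weights = varPower(form = ~ I(day + 1)),
          data = mf, method = method,
          control = lmeControl(returnObject = FALSE)),
      error = function(e) stop("mixed-model fit failed: ",
                               conditionMessage(e), call. = FALSE))
    b <- nlme::fixef(fit)
    V <- as.matrix(vcov(fit))
    vc_raw <- nlme::VarCorr(fit)
    vars <- suppressWarnings(as.numeric(vc_raw[, "Variance"]))
    varcomp <- data.frame(grouping = rownames(vc_raw), name = rownames(vc_raw),
                          variance = vars, sd = sqrt(vars),
                          stringsAsFactors = FALSE)
    varcomp <- varcomp[is.finite(varcomp$variance), , drop = FALSE]
    singular <- any(varcomp$variance < 1e-10)
  } else {
    re <- if (random == "slope") "(day | mouse_id) + (1 | tumor_id)"
          else "(1 | mouse_id) + (1 | tumor_id)"
    ctrl <- lmerControl(check.conv.singular = "ignore",
                        check.conv.grad = "ignore",
                        check.conv.hess = "ignore")
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmer(formula(paste("y ~", fr$rhs, "+", re)), data = mf,
             REML = method == "REML", control = ctrl))),
      error = function(e) stop("mixed-model fit failed: ",
                               conditionMessage(e), call. = FALSE))
    b <- fixef(fit)
    V <- as.matrix(vcov(fit))
    vc <- as.data.frame(VarCorr(fit))
    vc <- vc[is.na(vc$var2), , drop = FALSE]
    varcomp <- data.frame(grouping = vc$grp,
                          name = ifelse(is.na(vc$var1), "sd", vc$var1),
                          variance = vc$vcov, sd = vc$sdcor,
                          stringsAsFactors = FALSE)
    singular <- isSingular(fit)
  }
  se <- sqrt(diag(V))
  z <- unname(b) / se
  fixed <- data.frame(term = names(b), estimate = unname(b), se = se,
                      z = z, p = 2 * pnorm(-abs(z)),
                      row.names = NULL, stringsAsFactors = FALSE)
  ll <- logLik(fit)
  new("LmmFit", model = fit, fixed = fixed, varcomp = varcomp,
      logLik = as.numeric(ll), aic = AIC(fit), bic = BIC(fit),
      spec = list(outcome = outcome, piecewise = piecewise,
                  knot = if (piecewise) knot else NA_real_,
                  random = random, heteroscedastic = heteroscedastic,
                  method = method, groups = fr$groups,
                  rhs = fr$rhs, day_range = range(mf$day),
                  singular = singular, n_par = attr(ll, "df"),
                  n_obs = nrow(mf)),
      data = mf)
}

#' Wald test of the post-knot slope change between two groups
#'
#' For a piecewise fit, tests whether the post-knot slope increments of two
#' groups differ: the contrast `h_<group1> - h_<group2>` with its delta-method
#' standard error and two-sided normal p-value. Contrasting a group with
#' itself gives estimate 0.
#'
#' @param fit a piecewise [LmmFit-class].
#' @param group1,group2 group names among the fit's groups.
#' @return list: estimate (per day), se, z, p_value, groups.
#' @export
testSlopeChange <- function(fit, group1, group2) {
  stopifnot(is(fit, "LmmFit"))
  if (!isTRUE(fit@spec$piecewise))
    stop("testSlopeChange requires a piecewise fit")
  g1 <- tolower(group1); g2 <- tolower(group2)
  terms_h <- paste0("h_", c(g1, g2))
  missing_g <- c(g1, g2)[!terms_h %in% fit@fixed$term]
  if (length(missing_g))
    stop("group '", missing_g[1L], "' is not part of the fit")
  b <- setNames(fit@fixed$estimate, fit@fixed$term)
  cvec <- setNames(numeric(nrow(fit@fixed)), fit@fixed$term)
  cvec[paste0("h_", g1)] <- cvec[paste0("h_", g1)] + 1
  cvec[paste0("h_", g2)] <- cvec[paste0("h_", g2)] - 1
  V <- as.matrix(vcov(fit@model))
  est <- sum(cvec * b)
  se <- sqrt(drop(t(cvec) %*% V %*% cvec))
  z <- if (se > 0) est / se else 0
  list(estimate = est, se = se, z = z,
       p_value = if (se > 0) 2 * pnorm(-abs(z)) else 1,
       groups = c(g1, g2))
}

#' Rank fitted models by information criteria
#'
#' Tabulates log-likelihood, AIC and BIC of several fits of the same outcome
#' on the same data and sorts by AIC. REML likelihoods are not comparable
#' across different fixed-effect structures, so mixing REML fits with
#' differing fixed effects is an error (refit with ML).
#'
#' @param ... [LmmFit-class] objects (or a single list of them).
#' @return data.frame (model, k, logLik, AIC, BIC) sorted by AIC.
#' @export
compareModels <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) && !is(fits[[1L]], "LmmFit"))
    fits <- fits[[1L]]
  if (!length(fits) || !all(vapply(fits, is, logical(1), "LmmFit")))
    stop("compareModels expects LmmFit objects")
  outcomes <- vapply(fits, function(f) f@spec$outcome, character(1))
  nobs <- vapply(fits, function(f) f@spec$n_obs, numeric(1))
  if (length(unique(outcomes)) > 1L || length(unique(nobs)) > 1L)
    stop("models must be fitted to the same outcome and data")
  rhs <- vapply(fits, function(f) f@spec$rhs, character(1))
  reml <- vapply(fits, function(f) f@spec$method == "REML", logical(1))
  if (any(reml) && length(unique(rhs)) > 1L)
    stop("REML fits with differing fixed effects are not comparable; refit with ML")
  nm <- names(fits)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- paste0("model", seq_along(fits))
  out <- data.frame(model = nm,
                    k = vapply(fits, function(f) f@spec$n_par, numeric(1)),
                    logLik = vapply(fits, function(f) f@logLik, numeric(1)),
                    AIC = vapply(fits, function(f) f@aic, numeric(1)),
                    BIC = vapply(fits, function(f) f@bic, numeric(1)),
                    stringsAsFactors = FALSE)
  out[order(out$AIC), , drop = FALSE]
}

#' Population-average group trajectories with pointwise confidence bounds
#'
#' Evaluates the fitted fixed-effect mean of every group over a day grid with
#' delta-method 95 percent pointwise confidence bounds. Days outside the
#' observed range are allowed but flagged as extrapolation.
#'
#' @param fit an [LmmFit-class].
#' @param days numeric day grid (default: observed days).
#' @param level confidence level (default 0.95).
#' @return data.frame (group, day, estimate, se, lower, upper, extrapolated).
#' @export
predictGroupTrajectories <- function(fit, days = NULL, level = 0.95) {
  stopifnot(is(fit, "LmmFit"))
  if (is.null(days)) days <- sort(unique(fit@data$day))
  groups <- fit@spec$groups
  nd <- expand.grid(day = days, group = factor(groups, levels = groups))
  if (isTRUE(fit@spec$piecewise)) {
    for (lev in groups)
      nd[[paste0("h_", lev)]] <-
        pmax(0, nd$day - fit@spec$knot) * (nd$group == lev)
  }
  X <- model.matrix(formula(paste("~", fit@spec$rhs)), nd)
  b <- setNames(fit@fixed$estimate, fit@fixed$term)
  X <- X[, fit@fixed$term, drop = FALSE]
  V <- as.matrix(vcov(fit@model))
  est <- drop(X %*% b)
  se <- sqrt(rowSums((X %*% V) * X))
  zq <- qnorm(1 - (1 - level) / 2)
  rng <- fit@spec$day_range
  data.frame(group = as.character(nd$group), day = nd$day,
             estimate = est, se = se,
             lower = est - zq * se, upper = est + zq * se,
             extrapolated = nd$day < rng[1L] | nd$day > rng[2L],
             row.names = NULL, stringsAsFactors = FALSE)
}
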