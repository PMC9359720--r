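# Labelled oximetry fixture: growth cohort + trajectories with truth groups.
oxi_fixture <- function(seed = 1, n_control = 8, n_treated = 8,
                        responder_fraction = 0.5, oxi_cfg = oximetrySimConfig()) {
  co <- simulateGrowthCohort(growthSimConfig(
    n_control = n_control, n_treated = n_treated,
    responder_fraction = responder_fraction, seed = seed))
  oxi <- simulateOximetryTrajectories(oxi_cfg, co, seed = seed + 1)
  oxi
}

test_that("the piecewise design has a shared pre-knot slope and group hinges", {
  X <- piecewiseDesign(c(14, 28), c("responder", "responder"), knot = 21)
  # before the knot every group-specific column is zero
  expect_equal(unname(X[1, c("h_responder")]), 0)
  # after the knot the hinge carries day - knot in the unit's group column
  expect_equal(unname(X[2, "h_responder"]), 7)
  expect_equal(unname(X[, "day"]), c(14, 28))
  X3 <- piecewiseDesign(c(0, 28, 35), c("control", "nonresponder", "responder"))
  expect_equal(unname(X3[2, "h_nonresponder"]), 7)
  expect_equal(unname(X3[2, c("h_control", "h_responder")]), c(0, 0))
  expect_error(piecewiseDesign(1, "bev"), "allowed levels")
})

test_that("group vocabulary outside the three analysis levels is rejected", {
  oxi <- oxi_fixture()
  oxi$group[1] <- "mystery"
  expect_error(fitLmm(oxi, "so2"), "mystery")
})

test_that("with zero random-effect variance, fixed effects equal OLS", {
  co <- simulateGrowthCohort(growthSimConfig(
    n_control = 6, n_treated = 6, responder_fraction = 0.5,
    sd_mouse_intercept = 0, sd_tumor_intercept = 0, sd_mouse_slope = 0,
    sd_tumor_slope = 0, sd_residual = 0.2, seed = 44))
  co$group <- co$true_group
  fit <- fitLmm(co, "cube_root_volume")
  ols <- lm(cubeRoot(volume_mm3) ~ day * factor(group, patox:::.GROUPS),
            data = co)
  b_lmm <- setNames(fit@fixed$estimate, fit@fixed$term)
  expect_equal(unname(b_lmm["day"]), unname(coef(ols)["day"]),
               tolerance = 1e-5)
  expect_equal(unname(b_lmm["(Intercept)"]), unname(coef(ols)["(Intercept)"]),
               tolerance = 1e-5)
  # the estimated random-effect variances are small next to the residual
  vc <- varianceComponents(fit)
  expect_lt(max(vc$variance[vc$grouping != "Residual"]),
            0.1 * vc$variance[vc$grouping == "Residual"])
})

test_that("REML and ML fixed effects agree on a large balanced cohort", {
  co <- simulateGrowthCohort(growthSimConfig(n_control = 50, n_treated = 50,
                                             responder_fraction = 0.5,
                                             seed = 10))
  co$group <- co$true_group
  f_reml <- fitLmm(co, "cube_root_volume", method = "REML")
  f_ml <- fitLmm(co, "cube_root_volume", method = "ML")
  rel <- abs(f_reml@fixed$estimate - f_ml@fixed$estimate) /
    pmax(abs(f_reml@fixed$estimate), 1e-8)
  expect_lt(max(rel), 0.01)
})

test_that("clustered data inflate dependence-aware standard errors over OLS", {
  co <- simulateGrowthCohort(growthSimConfig(n_control = 10, n_treated = 10,
                                             responder_fraction = 0,
                                             sd_mouse_intercept = 1.5,
                                             seed = 3))
  co$group <- co$true_group
  fit <- fitLmm(co, "cube_root_volume")
  ols <- lm(cubeRoot(volume_mm3) ~ day * factor(group), data = co)
  se_lmm <- fit@fixed$se[fit@fixed$term == "(Intercept)"]
  se_ols <- summary(ols)$coefficients["(Intercept)", "Std. Error"]
  expect_gt(se_lmm, se_ols)
})

test_that("slope-change contrasts behave at the edges", {
  oxi <- oxi_fixture(seed = 6)
  fit <- fitLmm(oxi, "so2", piecewise = TRUE, knot = 21)
  same <- testSlopeChange(fit, "responder", "responder")
  expect_equal(same$estimate, 0)
  expect_equal(same$p_value, 1)
  expect_error(testSlopeChange(fit, "responder", "mystery"), "mystery")
  flat <- fitLmm(oxi, "so2")
  expect_error(testSlopeChange(flat, "responder", "control"), "piecewise")
})

test_that("a real slope change is detected with the right sign", {
  oxi <- oxi_fixture(seed = 16, n_control = 8, n_treated = 8)
  fit <- fitLmm(oxi, "so2", piecewise = TRUE, knot = 21)
  ts <- testSlopeChange(fit, "responder", "control")
  # configured post-knot slopes: responder -0.010, control +0.003
  expect_lt(ts$estimate, 0)
  expect_lt(ts$p_value, 1e-4)
  expect_equal(ts$estimate, -0.013, tolerance = 0.5)
})

test_that("sensitivity variants agree on the responder slope-change conclusion", {
  oxi <- oxi_fixture(seed = 26)
  base <- fitLmm(oxi, "so2", piecewise = TRUE)
  rs <- fitLmm(oxi, "so2", piecewise = TRUE, random = "slope")
  het <- fitLmm(oxi, "so2", piecewise = TRUE, heteroscedastic = TRUE)
  for (f in list(base, rs, het)) {
    ts <- testSlopeChange(f, "responder", "control")
    expect_lt(ts$estimate, 0)
    expect_lt(ts$p_value, 0.001)
  }
})

test_that("piecewise-generated data prefer the piecewise model by AIC", {
  wins <- vapply(1:60, function(i) {
    oxi <- oxi_fixture(seed = 6000 + i, n_control = 6, n_treated = 6)
    pw <- fitLmm(oxi, "so2", piecewise = TRUE, method = "ML")
    ln <- fitLmm(oxi, "so2", method = "ML")
    cmp <- compareModels(piecewise = pw, linear = ln)
    cmp$model[1] == "piecewise"
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("model comparison validates its inputs and its arithmetic", {
  oxi <- oxi_fixture(seed = 7)
  pw <- fitLmm(oxi, "so2", piecewise = TRUE, method = "ML")
  ln <- fitLmm(oxi, "so2", method = "ML")
  cmp <- compareModels(pw = pw, ln = ln)
  expect_equal(cmp$AIC, -2 * cmp$logLik + 2 * cmp$k, tolerance = 1e-8)
  tie <- compareModels(a = pw, b = pw)
  expect_equal(tie$AIC[1], tie$AIC[2])
  pw_reml <- fitLmm(oxi, "so2", piecewise = TRUE, method = "REML")
  ln_reml <- fitLmm(oxi, "so2", method = "REML")
  expect_error(compareModels(pw_reml, ln_reml), "REML")
})

test_that("predicted trajectories are continuous at the knot and collapse
           to the design-matrix mean at observed points", {
  oxi <- oxi_fixture(seed = 17)
  fit <- fitLmm(oxi, "so2", piecewise = TRUE, knot = 21)
  eps <- 1e-6
  tr <- predictGroupTrajectories(fit, days = c(21 - eps, 21, 21 + eps))
  for (g in unique(tr$group)) {
    v <- tr$estimate[tr$group == g]
    expect_lt(max(abs(diff(v))), 1e-4)
  }
  # at observed design points predictions equal X beta
  tr2 <- predictGroupTrajectories(fit, days = c(0, 14, 35))
  b <- setNames(fit@fixed$estimate, fit@fixed$term)
  row <- tr2[tr2$group == "responder" & tr2$day == 35, ]
  manual <- b["(Intercept)"] + b["day"] * 35 + b["h_responder"] * (35 - 21)
  expect_equal(row$estimate, unname(manual), tolerance = 1e-10)
  expect_false(any(tr2$extrapolated))
  tr3 <- predictGroupTrajectories(fit, days = c(42, 60))
  expect_equal(tr3$extrapolated[tr3$day == 60], rep(TRUE, sum(tr3$day == 60)))
})

test_that("confidence bounds shrink with sample size and vanish without noise", {
  width_for <- function(n) {
    oxi <- oxi_fixture(seed = 33, n_control = n, n_treated = n)
    fit <- fitLmm(oxi, "so2", piecewise = TRUE)
    tr <- predictGroupTrajectories(fit, days = 42)
    mean(tr$upper - tr$lower)
  }
  expect_gt(width_for(5), width_for(20))
  # zero-noise data collapse the bounds onto the mean line
  co <- simulateGrowthCohort(growthSimConfig(n_control = 4, n_treated = 4,
                                             responder_fraction = 0.5))
  oxi0 <- simulateOximetryTrajectories(
    oximetrySimConfig(so2_baseline_sd = 0, thb_baseline_sd = 0, sd_mouse = 0,
                      sd_tumor = 0, sd_residual = 0), co)
  fit0 <- fitLmm(oxi0, "so2", piecewise = TRUE)
  tr0 <- predictGroupTrajectories(fit0)
  expect_lt(max(tr0$upper - tr0$lower), 1e-4)
})

test_that("thb_normalized fits run through the same machinery", {
  oxi <- oxi_fixture(seed = 51)
  fit <- fitLmm(oxi, "thb_normalized", piecewise = TRUE)
  expect_s4_class(fit, "LmmFit")
  expect_true(all(varianceComponents(fit)$variance >= 0))
})
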