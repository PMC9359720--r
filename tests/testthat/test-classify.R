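test_that("cube-root transform is exact and invertible", {
  expect_equal(cubeRoot(1000), 10)
  expect_equal(cubeRoot(0), 0)
  expect_error(cubeRoot(-1), "non-negative")
  set.seed(1)
  for (i in 1:100) {
    v <- runif(8, 0, 3000)
    expect_equal(cubeRoot(v)^3, v, tolerance = 1e-12)
  }
})

test_that("growth slopes are recovered exactly from analytic series", {
  t <- c(0, 7, 14)
  f <- fitGrowthSlope(t, (1 + 0.1 * t)^3)
  expect_equal(f$slope, 0.1, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  # constant series
  f0 <- fitGrowthSlope(c(0, 7, 14), rep(1000, 3))
  expect_equal(f0$slope, 0)
  # two points define the line exactly
  f2 <- fitGrowthSlope(c(0, 7), c(8, 27))
  expect_equal(f2$r_squared, 1)
  expect_equal(f2$slope, (3 - 2) / 7)
  expect_error(fitGrowthSlope(c(7, 7), c(1, 2)), "identical")
  expect_error(fitGrowthSlope(7, 1), "2 observations")
})

test_that("mouse-level slopes pool the mouse's tumors into one fit", {
  co <- data.frame(mouse_id = "M1", tumor_id = rep(c("T1", "T2"), each = 3),
                   arm = "treated", day = rep(c(0, 7, 14), 2),
                   volume_mm3 = c((2 + 0.1 * c(0, 7, 14))^3,
                                  (4 + 0.1 * c(0, 7, 14))^3))
  sl_mouse <- fitGrowthSlopes(co, "mouse")
  sl_tumor <- fitGrowthSlopes(co, "tumor")
  expect_equal(nrow(sl_mouse), 1)
  expect_equal(nrow(sl_tumor), 2)
  expect_equal(sl_mouse$slope, 0.1, tolerance = 1e-10)
  expect_equal(sl_tumor$slope, c(0.1, 0.1), tolerance = 1e-10)
})

test_that("the threshold rule uses a strict inequality at 0.05", {
  expect_equal(thresholdClassify(0), "responder")
  expect_equal(thresholdClassify(0.05), "nonresponder")
  expect_equal(thresholdClassify(0.12), "nonresponder")
  expect_equal(thresholdClassify(0.049999), "responder")
})

test_that("classification commutes with unit changes when the cut is rescaled", {
  set.seed(4)
  t <- seq(0, 42, 7)
  slopes_mm3 <- runif(20, 0, 0.12)
  for (i in seq_along(slopes_mm3)) {
    v_mm3 <- (6 + slopes_mm3[i] * t)^3
    v_cm3 <- v_mm3 / 1000                    # volumes re-expressed in cm^3
    s1 <- fitGrowthSlope(t, v_mm3)$slope
    s2 <- fitGrowthSlope(t, v_cm3)$slope
    expect_equal(s2, s1 / 10, tolerance = 1e-9)
    expect_equal(thresholdClassify(s2, 0.05 / 10), thresholdClassify(s1, 0.05))
  }
})

test_that("cube-root-generated cohorts are linearized best by the cube root", {
  wins <- vapply(1:100, function(i) {
    co <- simulateGrowthCohort(growthSimConfig(n_control = 4, n_treated = 4,
                                               responder_fraction = 0,
                                               sd_residual = 0.15,
                                               seed = 900 + i))
    compareGrowthTransforms(co)$winner == "cuberoot"
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("exponentially generated cohorts are linearized best by the log", {
  wins <- vapply(1:100, function(i) {
    set.seed(1300 + i)
    t <- seq(0, 42, 7)
    co <- do.call(rbind, lapply(1:8, function(k) {
      rate <- rnorm(1, 0.08, 0.01)
      data.frame(mouse_id = sprintf("M%d", k),
                 tumor_id = sprintf("M%d_T1", k), arm = "control",
                 day = t,
                 volume_mm3 = 500 * exp(rate * t + rnorm(length(t), 0, 0.05)))
    }))
    compareGrowthTransforms(co)$winner == "log"
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("noiseless cube-root-linear series has cube-root r-squared of 1", {
  t <- seq(0, 42, 7)
  co <- data.frame(mouse_id = "M1", tumor_id = "M1_T1", arm = "control",
                   day = t, volume_mm3 = (5 + 0.08 * t)^3)
  rep <- compareGrowthTransforms(co)
  expect_equal(rep$per_series$r2_cuberoot, 1, tolerance = 1e-12)
  expect_equal(rep$winner, "cuberoot")
})

test_that("series with zero volumes are excluded from the log fit with warning", {
  t <- c(0, 7, 14)
  co <- rbind(
    data.frame(mouse_id = "M1", tumor_id = "T1", arm = "control", day = t,
               volume_mm3 = c(0, 100, 200)),
    data.frame(mouse_id = "M2", tumor_id = "T2", arm = "control", day = t,
               volume_mm3 = (5 + 0.1 * t)^3))
  expect_warning(rep <- compareGrowthTransforms(co), "excluded")
  expect_equal(rep$n_log_excluded, 1L)
  expect_true(is.na(rep$per_series$r2_log[rep$per_series$unit_id == "T1"]))
})

test_that("the significance rule flags more control-like units as controls grow", {
  set.seed(6)
  # nonresponder slopes drawn from the control distribution
  treated <- rnorm(2000, 0.08, 0.02)
  flag_rate <- vapply(c(4, 64), function(nc) {
    mean(vapply(1:200, function(i) {
      ctl <- rnorm(nc, 0.08, 0.02)
      mean(significanceClassify(treated[1:10 + (i %% 100)], ctl) == "responder")
    }, numeric(1)))
  }, numeric(1))
  expect_gt(flag_rate[2], flag_rate[1])
})
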