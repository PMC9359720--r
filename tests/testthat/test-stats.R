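test_that("the pooled t test matches the textbook formula", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  res <- ttestAuto(x, y)
  # hand-computed pooled statistic
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_equal(res$method, "student")
})

test_that("identical samples give statistic 0 and p 1", {
  x <- c(2, 4, 6)
  res <- ttestAuto(x, x)
  expect_equal(res$p_value, 1)
  expect_equal(unname(res$statistic), 0)
  resp <- ttestAuto(x, x, paired = TRUE)
  expect_equal(resp$p_value, 1)
  expect_equal(resp$statistic, 0)
  # constant equal groups fall back to the stated convention
  resc <- ttestAuto(c(1, 1, 1), c(1, 1, 1))
  expect_equal(resc$p_value, 1)
  expect_equal(resc$statistic, 0)
})

test_that("the variance pretest routes unequal variances to Welch", {
  picks <- vapply(1:200, function(i) {
    set.seed(7000 + i)
    ttestAuto(rnorm(15, 0, 1), rnorm(15, 0, 5))$method
  }, character(1))
  expect_gte(mean(picks == "welch"), 0.95)
  # equal variances and sizes keep Student, and the two statistics coincide
  set.seed(2)
  x <- rnorm(12); y <- rnorm(12, 0.5)
  st <- t.test(x, y, var.equal = TRUE)
  we <- t.test(x, y, var.equal = FALSE)
  expect_equal(unname(st$statistic), unname(we$statistic), tolerance = 1e-12)
})

test_that("paired tests validate their inputs", {
  expect_error(ttestAuto(1:3, 1:4, paired = TRUE), "equal-length")
  expect_error(ttestAuto(1, 1:2), "at least 2")
})

test_that("pearson correlation matches its definition", {
  expect_equal(pearsonTest(1:10, 2 * (1:10))$r, 1, tolerance = 1e-12)
  expect_equal(pearsonTest(1:10, -(1:10))$r, -1, tolerance = 1e-12)
  set.seed(5)
  x <- rnorm(20); y <- rnorm(20)
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonTest(x, y)$r, r_def, tolerance = 1e-12)
  expect_error(pearsonTest(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearsonTest(1:2, 1:2), "3 pairs")
})

test_that("the log-rank statistic matches the hypergeometric hand calculation", {
  time <- c(1, 2, 3, 4)
  event <- c(1, 1, 1, 1)
  group <- c("A", "A", "B", "B")
  res <- logrankTest(time, event, group)
  expect_equal(res$chi_square, oracle_logrank_chisq(time, event, group),
               tolerance = 1e-6)
  expect_equal(res$df, 1)
  # identical survival in both groups: statistic 0
  t2 <- rep(c(3, 5, 8), 2); e2 <- rep(c(1, 0, 1), 2)
  g2 <- rep(c("A", "B"), each = 3)
  expect_lt(logrankTest(t2, e2, g2)$chi_square, 1e-10)
  expect_error(logrankTest(c(1, 2), c(0, 0), c("A", "B")), "censored")
})

test_that("log-rank is invariant to group relabeling and holds its level", {
  set.seed(9)
  time <- rexp(40); event <- rbinom(40, 1, 0.8)
  group <- rep(c("A", "B"), 20)
  a <- logrankTest(time, event, group)$chi_square
  b <- logrankTest(time, event, ifelse(group == "A", "B", "A"))$chi_square
  expect_equal(a, b, tolerance = 1e-12)
  # equal-hazard groups reject at about the nominal level
  rej <- vapply(1:400, function(i) {
    set.seed(20000 + i)
    tt <- rexp(40, 0.2)
    logrankTest(tt, rep(1, 40), rep(c("A", "B"), 20))$p_value < 0.05
  }, logical(1))
  mc <- 3 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(rej) - 0.05), mc + 0.01)
})

test_that("Kaplan-Meier curves are non-increasing step functions from 1", {
  set.seed(12)
  st <- simulateSurvival(simulateGrowthCohort(growthSimConfig(seed = 4)))
  res <- logrankTest(st$time_days, st$event, st$group)
  for (g in unique(res$km$group)) {
    s <- res$km$surv[res$km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(max(s), 1)
    expect_gte(min(s), 0)
  }
})

test_that("zero effect size yields power at the nominal level", {
  pw <- mcPower(0.5, 0.5, 0.05, 0.05, icc = 0.3, n_mice = 6, R = 1000,
                seed = 3)
  expect_lt(abs(pw$grid$power - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.01)
})

test_that("power is non-decreasing in sample size up to Monte Carlo error", {
  pw <- mcPower(0.50, 0.42, 0.06, 0.06, icc = 0.3,
                n_mice = c(4, 8, 12, 16), R = 800, seed = 11)
  p <- pw$grid$power
  expect_true(all(diff(p) > -0.05))
  expect_gt(p[4], p[1])
})

test_that("independent tumors match the closed-form two-sample power", {
  delta <- 0.08; sdv <- 0.06; n <- 12
  pw <- mcPower(0.5, 0.5 + delta, sdv, sdv, icc = 0, n_mice = n,
                tumors_per_mouse = 1, R = 2500, seed = 21)
  closed <- power.t.test(n = n, delta = delta, sd = sdv)$power
  expect_lt(abs(pw$grid$power - closed), 3 * sqrt(closed * (1 - closed) / 2500) + 0.01)
})

test_that("mcPower validates the correlation and replicate count", {
  expect_error(mcPower(1, 0, 1, 1, icc = 1), "icc")
  expect_error(mcPower(1, 0, 1, 1, icc = -0.1), "icc")
  expect_error(mcPower(1, 0, 1, 1, R = 0), "R")
})
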