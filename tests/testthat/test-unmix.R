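test_that("wavelength selection keeps the 700-900 nm unmixing subset", {
  st <- multispectralStack(array(0, c(2, 2, 14)), acquisitionWavelengths())
  sel <- selectWavelengths(st, 700, 900)
  expect_equal(wavelengths(sel), c(700, 725, 750, 775, 800, 825, 850, 900))
  expect_equal(wavelengths(selectWavelengths(st, 0, Inf)),
               acquisitionWavelengths())
  expect_error(selectWavelengths(st, 1200, 1300), "fewer than 2 wavelengths")
  expect_error(selectWavelengths(st, 900, 700), "smaller")
})

test_that("an identity extinction matrix returns the raw two-band signal", {
  tab <- extinctionTable(c(700, 800), eps_hbo2 = c(1, 0), eps_hb = c(0, 1))
  px <- array(c(2, 3), c(1, 1, 2))
  um <- unmixPixels(multispectralStack(px, c(700, 800)), tab)
  expect_equal(hbo2Map(um)[1, 1], 2)
  expect_equal(hbMap(um)[1, 1], 3)
  expect_equal(residualMap(um)[1, 1], 0)
})

test_that("collinear extinction spectra are rejected", {
  tab <- extinctionTable(c(700, 800), eps_hbo2 = c(1, 2), eps_hb = c(2, 4))
  st <- multispectralStack(array(1, c(1, 1, 2)), c(700, 800))
  expect_error(unmixPixels(st, tab), "rank-deficient|collinear")
})

test_that("wavelengths outside the extinction table are named in the error", {
  st <- multispectralStack(array(1, c(1, 1, 2)), c(700, 1250))
  expect_error(unmixPixels(st), "1250")
})

test_that("noiseless constant-fluence phantoms round-trip through unmixing", {
  ph <- simulatePhantom(phantomConfig(noise_sd = 0, fluence = "constant"))
  um <- unmixPixels(selectWavelengths(ph$stack, 700, 900))
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-12))
  expect_lt(rel(hbo2Map(um), ph$truth$c_hbo2), 1e-8)
  expect_lt(rel(hbMap(um), ph$truth$c_hb), 1e-8)
  # ground-truth oxygenation recovered through the ROI pipeline
  cfg <- phantomConfig(noise_sd = 0, tumor_so2 = 0.70)
  ph2 <- simulatePhantom(cfg)
  um2 <- unmixPixels(selectWavelengths(ph2$stack, 700, 900))
  rs <- roiStatistics(um2, ph2$masks$tumor)
  rr <- roiStatistics(um2, ph2$masks$reference)
  rec <- computeOximetry(rs$mean_hbo2, rs$mean_hb, rr$mean_hbo2, rr$mean_hb)
  expect_lt(abs(rec$so2_msot - 0.70), 1e-8)
})

test_that("a c_Hb-free noiseless phantom is proportional to the HbO2 spectrum", {
  cfg <- phantomConfig(noise_sd = 0, background_so2 = 1, tumor_so2 = 1,
                       reference_so2 = 1)
  ph <- simulatePhantom(cfg)
  eps <- patox:::.interpolateExtinction(hemoglobinExtinction(),
                                        wavelengths(ph$stack))
  px <- pixelArray(ph$stack)
  spectrum <- px[5, 5, ] / px[5, 5, 1]
  expect_equal(spectrum, eps[, "hbo2"] / eps[1, "hbo2"], tolerance = 1e-10)
})

test_that("seeded phantom noise is reproducible bit for bit", {
  cfg <- phantomConfig(noise_sd = 0.5, seed = 42)
  expect_identical(pixelArray(simulatePhantom(cfg)$stack),
                   pixelArray(simulatePhantom(cfg)$stack))
})

test_that("per-pixel unmixing equals the closed-form normal-equations solve", {
  cfg <- phantomConfig(noise_sd = 0.3, seed = 8)
  ph <- simulatePhantom(cfg)
  st <- selectWavelengths(ph$stack, 700, 900)
  um <- unmixPixels(st)
  eps <- patox:::.interpolateExtinction(hemoglobinExtinction(), wavelengths(st))
  set.seed(3)
  for (k in 1:10) {
    i <- sample(dim(pixelArray(st))[1], 1)
    j <- sample(dim(pixelArray(st))[2], 1)
    s <- pixelArray(st)[i, j, ]
    w <- solve(t(eps) %*% eps, t(eps) %*% s)   # independent 2x2 solve
    expect_equal(hbo2Map(um)[i, j], w[1], tolerance = 1e-10)
    expect_equal(hbMap(um)[i, j], w[2], tolerance = 1e-10)
  }
})

test_that("nonnegative unmixing clips negative weights optimally", {
  tab <- extinctionTable(c(700, 800), eps_hbo2 = c(1, 0), eps_hb = c(0, 1))
  px <- array(c(-2, 3), c(1, 1, 2))
  um <- unmixPixels(multispectralStack(px, c(700, 800)), tab,
                    nonnegative = TRUE)
  expect_equal(hbo2Map(um)[1, 1], 0)
  expect_equal(hbMap(um)[1, 1], 3)
  expect_equal(residualMap(um)[1, 1], 2)
})

test_that("ROI means equal a direct masked summation", {
  set.seed(11)
  m <- matrix(rnorm(64), 8, 8)
  um <- new("UnmixResult", hbo2 = m, hb = 2 * m, residual = abs(m))
  mask <- roiMask(matrix(rep(c(TRUE, FALSE), 32), 8, 8))
  rs <- roiStatistics(um, mask)
  expect_equal(rs$mean_hbo2, sum(m[maskMatrix(mask)]) / sum(maskMatrix(mask)))
  expect_equal(rs$mean_hb, 2 * rs$mean_hbo2)
  # uniform and checkerboard sanity values
  um2 <- new("UnmixResult", hbo2 = matrix(5, 2, 2),
             hb = matrix(c(0, 2, 2, 0), 2, 2), residual = matrix(0, 2, 2))
  rs2 <- roiStatistics(um2, roiMask(matrix(TRUE, 2, 2)))
  expect_equal(rs2$mean_hbo2, 5)
  expect_equal(rs2$mean_hb, 1)
  expect_error(roiMask(matrix(FALSE, 2, 2)), "empty")
})

test_that("oximetry records follow the ratio definitions and clamp policy", {
  rec <- computeOximetry(5, 5, 8, 2)
  expect_equal(rec$so2_msot, 0.5)
  expect_equal(rec$thb, 10)
  expect_equal(rec$thb_normalized, 1)
  expect_equal(computeOximetry(0, 3, 1, 1)$so2_msot, 0)
  # negative-to-zero clamping keeps SO2 in [0, 1]
  rec2 <- computeOximetry(-1, 3, 1, 1)
  expect_equal(rec2$so2_msot, 0)
  expect_true(rec2$valid)
  # non-positive tumor THb flags the record invalid rather than reporting 0
  rec3 <- computeOximetry(-2, 0, 1, 1)
  expect_false(rec3$valid)
  expect_true(is.na(rec3$so2_msot))
  expect_error(computeOximetry(1, 1, -1, 0), "reference THb")
})

test_that("SO2 and normalized THb are invariant to global signal rescaling", {
  ph <- simulatePhantom(phantomConfig(noise_sd = 0.2, seed = 21))
  st <- selectWavelengths(ph$stack, 700, 900)
  record_of <- function(stack) {
    um <- unmixPixels(stack)
    rs <- roiStatistics(um, ph$masks$tumor)
    rr <- roiStatistics(um, ph$masks$reference)
    computeOximetry(rs$mean_hbo2, rs$mean_hb, rr$mean_hbo2, rr$mean_hb)
  }
  base <- record_of(st)
  scaled <- record_of(multispectralStack(pixelArray(st) * 7.3,
                                         wavelengths(st)))
  expect_equal(scaled$so2_msot, base$so2_msot, tolerance = 1e-12)
  expect_equal(scaled$thb_normalized, base$thb_normalized, tolerance = 1e-12)
})

test_that("depth-dependent fluence biases apparent SO2 while constant does not", {
  roi_so2 <- function(fluence) {
    ph <- simulatePhantom(phantomConfig(noise_sd = 0, fluence = fluence,
                                        mu_eff = 0.05))
    um <- unmixPixels(selectWavelengths(ph$stack, 700, 900))
    rs <- roiStatistics(um, ph$masks$tumor)
    rec <- computeOximetry(rs$mean_hbo2, rs$mean_hb, 1, 1)
    rec$so2_msot
  }
  truth <- 0.40
  expect_lt(abs(roi_so2("constant") - truth), 1e-8)
  # spectral coloring of the illumination with depth biases the apparent SO2
  expect_gt(abs(roi_so2("exponential") - truth), 0.005)
})
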