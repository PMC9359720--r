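#' @include extinction.R
NULL

.ellipseMask <- function(shape, center, radii) {
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  c_ <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  ((r - center[1L]) / radii[1L])^2 + ((c_ - center[2L]) / radii[2L])^2 <= 1
}

#' Configuration of the multispectral phantom generator
#'
#' Describes a synthetic 2-D multispectral phantom built by a hemoglobin
#' forward model: per pixel, signal at wavelength lambda is
#' `fluence * (eps_HbO2(lambda) * c_HbO2 + eps_Hb(lambda) * c_Hb)` plus
#' additive Gaussian noise. Concentration fields are piecewise constant over
#' a background, an elliptical "tumor" and a circular "reference vessel"
#' region, each parametrized by total hemoglobin concentration and oxygen
#' saturation (so `c_HbO2 = so2 * thb`, `c_Hb = (1 - so2) * thb`); full
#' concentration maps can be supplied instead.
#'
#' The default fluence is constant (= 1), under which apparent oxygenation is
#' unbiased. The "exponential" option attenuates the illumination with depth
#' (rows) as `exp(-mu_eff(lambda) * (row - 1))`, with the effective
#' attenuation scaled by the background absorption spectrum at each
#' wavelength (spectral coloring). Because the illumination spectrum then
#' changes with depth, unmixing against the undistorted extinction spectra is
#' biased — demonstrating why uncorrected oxygenation estimates are only
#' apparent metrics.
#'
#' @param image_shape c(rows, cols) in pixels.
#' @param wavelengths acquisition wavelengths (nm); must lie within the
#'   extinction table range.
#' @param tumor_center,tumor_radii ellipse center (row, col) and radii in
#'   pixels.
#' @param reference_center,reference_radius disc center and radius in pixels.
#' @param background_so2,background_thb,tumor_so2,tumor_thb,reference_so2,reference_thb
#'   region oxygen saturation (in `[0, 1]`) and total hemoglobin concentration
#'   (arbitrary units, >= 0).
#' @param c_hbo2_map,c_hb_map optional explicit concentration matrices
#'   overriding the region parametrization.
#' @param fluence "constant" or "exponential".
#' @param mu_eff effective attenuation per pixel for the exponential fluence.
#' @param noise_sd additive Gaussian noise SD on the signal (a.u.). Negative
#'   noisy signals are kept, not clamped; unmixing must tolerate them.
#' @param seed integer seed.
#' @return A list of class `PhantomConfig`.
#' @seealso [simulatePhantom()]
#' @export
phantomConfig <- function(image_shape = c(48, 48),
                          wavelengths = acquisitionWavelengths(),
                          tumor_center = c(30, 16), tumor_radii = c(10, 8),
                          reference_center = c(12, 36), reference_radius = 5,
                          background_so2 = 0.70, background_thb = 0.2,
                          tumor_so2 = 0.40, tumor_thb = 1.0,
                          reference_so2 = 0.90, reference_thb = 2.0,
                          c_hbo2_map = NULL, c_hb_map = NULL,
                          fluence = c("constant", "exponential"),
                          mu_eff = 0.02, noise_sd = 0, seed = 1L) {
  fluence <- match.arg(fluence)
  if (length(image_shape) != 2L || any(image_shape < 4))
    stop("invalid 'image_shape': need c(rows, cols) with at least 4 pixels each")
  for (v in c("background_so2", "tumor_so2", "reference_so2"))
    if (get(v) < 0 || get(v) > 1)
      stop("invalid '", v, "': oxygen saturation must lie in [0, 1]")
  for (v in c("background_thb", "tumor_thb", "reference_thb"))
    .checkPositiveScalar(get(v), v, allow_zero = TRUE)
  .checkPositiveScalar(noise_sd, "noise_sd", allow_zero = TRUE)
  tmask <- .ellipseMask(image_shape, tumor_center, tumor_radii)
  rmask <- .ellipseMask(image_shape, reference_center,
                        rep(reference_radius, 2L))
  if (!any(tmask) || !any(rmask))
    stop("invalid ROI geometry: tumor or reference region is empty")
  edge <- function(msk) any(msk[c(1L, nrow(msk)), ]) || any(msk[, c(1L, ncol(msk))])
  if (edge(tmask) || edge(rmask))
    stop("invalid ROI geometry: regions must lie within image bounds")
  if (any(tmask & rmask))
    stop("invalid ROI geometry: tumor and reference regions overlap")
  structure(list(image_shape = as.integer(image_shape),
                 wavelengths = sort(as.numeric(wavelengths)),
                 tumor_mask = tmask, reference_mask = rmask,
                 background_so2 = background_so2, background_thb = background_thb,
                 tumor_so2 = tumor_so2, tumor_thb = tumor_thb,
                 reference_so2 = reference_so2, reference_thb = reference_thb,
                 c_hbo2_map = c_hbo2_map, c_hb_map = c_hb_map,
                 fluence = fluence, mu_eff = mu_eff,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "PhantomConfig")
}

#' Simulate a multispectral phantom stack
#'
#' Runs the hemoglobin-extinction forward model of a [phantomConfig()] and
#' returns the multispectral stack, the tumor/reference ROI masks, and the
#' ground-truth maps (per-pixel chromophore concentrations, oxygen saturation
#' `c_HbO2 / (c_HbO2 + c_Hb)`, and the fluence field).
#'
#' @param config a `PhantomConfig`.
#' @param table an [ExtinctionTable-class]; defaults to the bundled spectra.
#' @param seed optional integer overriding `config$seed`.
#' @return list with elements `stack` ([MultispectralStack-class]), `masks`
#'   (list of [RoiMask-class]), and `truth` (list: c_hbo2, c_hb, so2, fluence).
#' @examples
#' ph <- simulatePhantom(phantomConfig(noise_sd = 0))
#' ph$stack
#' @export
simulatePhantom <- function(config, table = hemoglobinExtinction(), seed = NULL) {
  if (!inherits(config, "PhantomConfig"))
    stop("'config' must come from phantomConfig()")
  eps <- .interpolateExtinction(table, config$wavelengths)
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  shp <- config$image_shape
  if (!is.null(config$c_hbo2_map) || !is.null(config$c_hb_map)) {
    c_hbo2 <- config$c_hbo2_map; c_hb <- config$c_hb_map
    if (is.null(c_hbo2) || is.null(c_hb) ||
        !identical(dim(c_hbo2), dim(c_hb)) ||
        !identical(as.integer(dim(c_hbo2)), shp))
      stop("c_hbo2_map and c_hb_map must both be given with shape image_shape")
  } else {
    so2 <- matrix(config$background_so2, shp[1L], shp[2L])
    thb <- matrix(config$background_thb, shp[1L], shp[2L])
    so2[config$tumor_mask] <- config$tumor_so2
    thb[config$tumor_mask] <- config$tumor_thb
    so2[config$reference_mask] <- config$reference_so2
    thb[config$reference_mask] <- config$reference_thb
    c_hbo2 <- so2 * thb
    c_hb <- (1 - so2) * thb
  }
  if (any(c_hbo2 < 0) || any(c_hb < 0))
    stop("ground-truth concentrations must be non-negative")
  # Fluence field: constant, or exponential-depth attenuation whose
  # effective mu scales with the background absorption spectrum (spectral
  # coloring) -- the mechanism that makes uncorrected SO2 an apparent metric.
  n_wl <- length(config$wavelengths)
  depth <- seq_len(shp[1L]) - 1
  if (config$fluence == "constant") {
    flu <- array(1, c(shp, n_wl))
  } else {
    a_bg <- eps[, "hbo2"] * mean(c_hbo2) + eps[, "hb"] * mean(c_hb)
    mu_l <- config$mu_eff * a_bg / max(a_bg)
    flu <- array(0, c(shp, n_wl))
    for (l in seq_len(n_wl))
      flu[, , l] <- matrix(exp(-mu_l[l] * depth), shp[1L], shp[2L])
  }
  pixels <- array(0, c(shp, n_wl))
  for (l in seq_len(n_wl)) {
    plane <- flu[, , l] * (eps[l, "hbo2"] * c_hbo2 + eps[l, "hb"] * c_hb)
    if (config$noise_sd > 0)
      plane <- plane + rnorm(length(plane), 0, config$noise_sd)
    pixels[, , l] <- plane
  }
  total <- c_hbo2 + c_hb
  so2_truth <- ifelse(total > 0, c_hbo2 / total, NA_real_)
  list(stack = multispectralStack(pixels, config$wavelengths,
                                  metadata = list(source = "simulatePhantom")),
       masks = list(tumor = roiMask(config$tumor_mask, "tumor"),
                    reference = roiMask(config$reference_mask, "reference")),
       truth = list(c_hbo2 = c_hbo2, c_hb = c_hb, so2 = so2_truth,
                    fluence = flu))
}
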