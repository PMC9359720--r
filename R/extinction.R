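#' @include AllClasses.R
NULL

#' Construct an extinction table
#'
#' @param wavelength numeric, strictly increasing wavelengths in nm.
#' @param eps_hbo2,eps_hb numeric, extinction values of oxy- and
#'   deoxyhemoglobin at each wavelength (consistent arbitrary units).
#' @return An [ExtinctionTable-class] object.
#' @examples
#' extinctionTable(c(750, 850), eps_hbo2 = c(518, 1058), eps_hb = c(1405, 691))
#' @export
extinctionTable <- function(wavelength, eps_hbo2, eps_hb) {
  new("ExtinctionTable", wavelength = as.numeric(wavelength),
      eps_hbo2 = as.numeric(eps_hbo2), eps_hb = as.numeric(eps_hb))
}

#' Bundled hemoglobin extinction spectra
#'
#' Loads the extinction table shipped with the package: smooth synthetic
#' oxy-/deoxyhemoglobin spectra of literature magnitude on a 2-nm grid from
#' 650 to 1100 nm (see the CSV header for provenance). The same table drives
#' the phantom forward model and the unmixing inverse, so noiseless phantoms
#' round-trip exactly.
#'
#' @return An [ExtinctionTable-class] covering 650-1100 nm.
#' @examples
#' tab <- hemoglobinExtinction()
#' range(wavelengths(tab))
#' @export
hemoglobinExtinction <- function() {
  path <- system.file("extdata", "hemoglobin_extinction_synthetic.csv",
                      package = "patox", mustWork = TRUE)
  tab <- read.csv(path, comment.char = "#")
  extinctionTable(tab$wavelength_nm, tab$eps_hbo2, tab$eps_hb)
}

#' The 14 standard acquisition wavelengths
#'
#' Wavelength grid (nm) of a typical small-animal multispectral optoacoustic
#' tomography acquisition spanning 700-1100 nm; linear unmixing conventionally
#' uses the 700-900 nm subset where the hemoglobin spectra dominate.
#'
#' @return numeric vector of 14 wavelengths in nm.
#' @examples
#' acquisitionWavelengths()
#' @export
acquisitionWavelengths <- function() {
  c(700, 725, 750, 775, 800, 825, 850, 900, 920, 950, 970, 1000, 1040, 1100)
}

# Interpolate an extinction table onto a target wavelength grid.
# Errors, naming the wavelength, if the grid leaves the tabulated range.
.interpolateExtinction <- function(table, wl) {
  lo <- min(table@wavelength); hi <- max(table@wavelength)
  bad <- wl[wl < lo | wl > hi]
  if (length(bad))
    stop("wavelength ", bad[1L], " nm outside the extinction table range [",
         lo, ", ", hi, "] nm")
  cbind(
    hbo2 = approx(table@wavelength, table@eps_hbo2, xout = wl)$y,
    hb   = approx(table@wavelength, table@eps_hb,   xout = wl)$y)
}

#' Construct a multispectral stack
#'
#' @param pixels 3-D numeric array (rows x cols x wavelengths) of
#'   photoacoustic signal in arbitrary units.
#' @param wavelengths numeric, acquisition wavelengths in nm (strictly
#'   increasing, one per plane).
#' @param metadata optional list of acquisition identifiers.
#' @return A [MultispectralStack-class] object.
#' @export
multispectralStack <- function(pixels, wavelengths, metadata = list()) {
  new("MultispectralStack", wavelengths = as.numeric(wavelengths),
      pixels = pixels, metadata = metadata)
}

#' Construct a region-of-interest mask
#'
#' @param mask logical matrix, TRUE inside the region.
#' @param name ROI name, conventionally "tumor" or "reference".
#' @return A [RoiMask-class] object.
#' @export
roiMask <- function(mask, name = "tumor") {
  new("RoiMask", name = name, mask = mask)
}
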