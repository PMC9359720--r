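#' @include patox-package.R
NULL

#' Tabulated hemoglobin extinction spectra
#'
#' Holds molar extinction values of oxyhemoglobin (HbO2) and deoxyhemoglobin
#' (Hb) on a strictly increasing wavelength grid. Units are arbitrary but must
#' be mutually consistent: linear spectral unmixing only uses the relative
#' spectral shapes, so any common scaling cancels.
#'
#' @slot wavelength numeric, strictly increasing wavelength grid in nm.
#' @slot eps_hbo2 numeric, extinction of HbO2 at each wavelength.
#' @slot eps_hb numeric, extinction of Hb at each wavelength.
#' @seealso [hemoglobinExtinction()] for the bundled table,
#'   [extinctionTable()] for the constructor.
#' @export
setClass("ExtinctionTable",
  representation(wavelength = "numeric", eps_hbo2 = "numeric", eps_hb = "numeric"))

setValidity("ExtinctionTable", function(object) {
  n <- length(object@wavelength)
  if (n < 1L) return("wavelength grid is empty")
  if (length(object@eps_hbo2) != n || length(object@eps_hb) != n)
    return("extinction vectors must match the wavelength grid length")
  if (n > 1L && any(diff(object@wavelength) <= 0))
    return("wavelengths must be strictly increasing")
  if (any(!is.finite(object@wavelength)) ||
      any(!is.finite(object@eps_hbo2)) || any(!is.finite(object@eps_hb)))
    return("wavelengths and extinction values must be finite")
  if (any(object@eps_hbo2 < 0) || any(object@eps_hb < 0))
    return("extinction values must be non-negative")
  TRUE
})

#' Multispectral photoacoustic image stack
#'
#' A single reconstructed 2-D tomographic slice acquired at several
#' wavelengths: a rows x cols x n_wavelengths array of photoacoustic signal in
#' arbitrary units, together with its wavelength grid.
#'
#' @slot wavelengths numeric, acquisition wavelengths in nm (one per image
#'   plane, strictly increasing).
#' @slot pixels 3-D numeric array, rows x cols x length(wavelengths).
#' @slot metadata list of free-form acquisition identifiers.
#' @seealso [multispectralStack()], [selectWavelengths()], [unmixPixels()]
#' @export
setClass("MultispectralStack",
  representation(wavelengths = "numeric", pixels = "array", metadata = "list"))

setValidity("MultispectralStack", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L) return("pixels must be a 3-D array (rows x cols x wavelengths)")
  if (d[3L] != length(object@wavelengths))
    return("third array dimension must equal the number of wavelengths")
  if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (any(!is.finite(object@pixels))) return("pixel values must be finite")
  TRUE
})

#' Region-of-interest mask
#'
#' A named boolean pixel mask delineating either the tumor cross-section or
#' the reference vessel region (abdominal aorta / vena cava) used for
#' normalization of total hemoglobin.
#'
#' @slot name character, ROI name (conventionally "tumor" or "reference").
#' @slot mask logical matrix, TRUE inside the ROI.
#' @seealso [roiMask()], [roiStatistics()]
#' @export
setClass("RoiMask", representation(name = "character", mask = "matrix"))

setValidity("RoiMask", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (any(is.na(object@mask))) return("mask must not contain NA")
  if (!any(object@mask)) return("mask is empty (no TRUE pixel)")
  TRUE
})

#' Per-pixel spectral unmixing result
#'
#' Least-squares decomposition of a multispectral stack into per-pixel HbO2
#' and Hb component weights (arbitrary units) plus the per-pixel residual
#' norm of the spectral fit.
#'
#' @slot hbo2 numeric matrix of oxyhemoglobin weights.
#' @slot hb numeric matrix of deoxyhemoglobin weights.
#' @slot residual numeric matrix of residual 2-norms.
#' @seealso [unmixPixels()], [roiStatistics()], [so2Map()]
#' @export
setClass("UnmixResult",
  representation(hbo2 = "matrix", hb = "matrix", residual = "matrix"))

setValidity("UnmixResult", function(object) {
  d <- dim(object@hbo2)
  if (!identical(dim(object@hb), d) || !identical(dim(object@residual), d))
    return("hbo2, hb and residual maps must share one shape")
  if (any(!is.finite(object@hbo2)) || any(!is.finite(object@hb)) ||
      any(!is.finite(object@residual)))
    return("unmixed maps must be finite")
  if (any(object@residual < 0)) return("residual norms must be non-negative")
  TRUE
})

#' Responder/nonresponder allocation state
#'
#' The converged (or final) state of the hard expectation-maximization
#' allocation of treated units to growth classes: per-unit labels, the -2
#' log-likelihood objective of the joint mixed-model fit, its trace across
#' iterations, and the fitted model parameters.
#'
#' @slot labels named character vector over treated units, values
#'   "responder"/"nonresponder".
#' @slot iteration integer, number of EM iterations performed.
#' @slot objective numeric, final -2 log-likelihood (ML) of the joint fit.
#' @slot trace numeric, objective after each M-step.
#' @slot params list of fitted parameters (fixed effects, variance
#'   components, residual SD) from the final M-step.
#' @slot converged logical, TRUE if labels reached a fixed point (or the
#'   objective change fell below tolerance) before the iteration cap.
#' @slot level character, "mouse" or "tumor".
#' @seealso [emAllocate()]
#' @export
setClass("AllocationState",
  representation(labels = "character", iteration = "integer",
    objective = "numeric", trace = "numeric", params = "list",
    converged = "logical", level = "character"))

setValidity("AllocationState", function(object) {
  if (length(object@labels) &&
      !all(object@labels %in% c("responder", "nonresponder")))
    return("labels must be 'responder' or 'nonresponder'")
  if (is.null(names(object@labels)) && length(object@labels))
    return("labels must be named by unit id")
  if (!is.finite(object@objective)) return("objective must be finite")
  if (!object@level %in% c("mouse", "tumor"))
    return("level must be 'mouse' or 'tumor'")
  TRUE
})

#' Fitted linear mixed model summary
#'
#' A fitted hierarchical linear mixed model for a longitudinal outcome
#' (cube-root tumor volume, SO2, or normalized THb), carrying Wald fixed-effect
#' inference, variance components, information criteria, the underlying fit
#' object, and the specification needed to rebuild the fixed-effect design for
#' prediction.
#'
#' @slot model the underlying `lme4::lmer` or `nlme::lme` fit.
#' @slot fixed data.frame with columns term, estimate, se, z, p (Wald normal).
#' @slot varcomp data.frame of variance components (grouping, name, variance, sd).
#' @slot logLik numeric log-likelihood (REML or ML per `spec$method`).
#' @slot aic,bic numeric information criteria.
#' @slot spec list: outcome, piecewise, knot, random, heteroscedastic, method,
#'   groups, day range, singular flag.
#' @slot data the modeling frame used for the fit.
#' @seealso [fitLmm()], [testSlopeChange()], [predictGroupTrajectories()],
#'   [compareModels()]
#' @export
setClass("LmmFit",
  representation(model = "ANY", fixed = "data.frame", varcomp = "data.frame",
    logLik = "numeric", aic = "numeric", bic = "numeric", spec = "list",
    data = "data.frame"))

setValidity("LmmFit", function(object) {
  if (!is.finite(object@logLik)) return("log-likelihood must be finite")
  if (any(object@varcomp$variance < 0)) return("variance components must be >= 0")
  k <- object@spec$n_par
  if (!is.null(k)) {
    if (abs(object@aic - (-2 * object@logLik + 2 * k)) > 1e-6)
      return("AIC inconsistent with log-likelihood and parameter count")
  }
  TRUE
})
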