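#' @include AllClasses.R
NULL

#' Accessors for patox S4 classes
#'
#' `wavelengths()` returns the wavelength grid of a stack or extinction table;
#' `pixelArray()` the raw signal array of a stack; `maskMatrix()` the logical
#' mask of an ROI; `hbo2Map()`, `hbMap()` and `residualMap()` the component
#' maps of an unmixing result; `allocationLabels()`, `objective()` and
#' `converged()` the state of an EM allocation; `fixedEffects()`,
#' `varianceComponents()` and `modelObject()` the pieces of a fitted mixed
#' model.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setMethod("wavelengths", "MultispectralStack", function(x) x@wavelengths)
#' @rdname accessors
#' @export
setMethod("wavelengths", "ExtinctionTable", function(x) x@wavelength)

#' @rdname accessors
#' @export
setGeneric("pixelArray", function(x) standardGeneric("pixelArray"))
#' @rdname accessors
#' @export
setMethod("pixelArray", "MultispectralStack", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setMethod("maskMatrix", "RoiMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("hbo2Map", function(x) standardGeneric("hbo2Map"))
#' @rdname accessors
#' @export
setMethod("hbo2Map", "UnmixResult", function(x) x@hbo2)

#' @rdname accessors
#' @export
setGeneric("hbMap", function(x) standardGeneric("hbMap"))
#' @rdname accessors
#' @export
setMethod("hbMap", "UnmixResult", function(x) x@hb)

#' @rdname accessors
#' @export
setGeneric("residualMap", function(x) standardGeneric("residualMap"))
#' @rdname accessors
#' @export
setMethod("residualMap", "UnmixResult", function(x) x@residual)

#' @rdname accessors
#' @export
setGeneric("allocationLabels", function(x) standardGeneric("allocationLabels"))
#' @rdname accessors
#' @export
setMethod("allocationLabels", "AllocationState", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("objective", function(x) standardGeneric("objective"))
#' @rdname accessors
#' @export
setMethod("objective", "AllocationState", function(x) x@objective)

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname accessors
#' @export
setMethod("converged", "AllocationState", function(x) x@converged)

#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))
#' @rdname accessors
#' @export
setMethod("fixedEffects", "LmmFit", function(x) x@fixed)

#' @rdname accessors
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))
#' @rdname accessors
#' @export
setMethod("varianceComponents", "LmmFit", function(x) x@varcomp)

#' @rdname accessors
#' @export
setGeneric("modelObject", function(x) standardGeneric("modelObject"))
#' @rdname accessors
#' @export
setMethod("modelObject", "LmmFit", function(x) x@model)

setMethod("show", "ExtinctionTable", function(object) {
  cat("ExtinctionTable:", length(object@wavelength), "wavelengths,",
      min(object@wavelength), "-", max(object@wavelength), "nm\n")
})

setMethod("show", "MultispectralStack", function(object) {
  d <- dim(object@pixels)
  cat("MultispectralStack:", d[1L], "x", d[2L], "pixels,",
      d[3L], "wavelengths (", min(object@wavelengths), "-",
      max(object@wavelengths), "nm )\n")
})

setMethod("show", "RoiMask", function(object) {
  cat("RoiMask '", object@name, "': ", sum(object@mask), " of ",
      length(object@mask), " pixels\n", sep = "")
})

setMethod("show", "UnmixResult", function(object) {
  d <- dim(object@hbo2)
  cat("UnmixResult:", d[1L], "x", d[2L], "pixels; mean residual norm",
      signif(mean(object@residual), 4), "\n")
})

setMethod("show", "AllocationState", function(object) {
  cat("AllocationState (", object@level, " level): ",
      sum(object@labels == "responder"), " responder / ",
      sum(object@labels == "nonresponder"), " nonresponder; ",
      object@iteration, " iterations; -2 logLik = ",
      signif(object@objective, 6),
      if (object@converged) " (converged)\n" else " (not converged)\n",
      sep = "")
})

setMethod("show", "LmmFit", function(object) {
  cat("LmmFit:", object@spec$outcome,
      if (isTRUE(object@spec$piecewise))
        paste0("(piecewise, knot day ", object@spec$knot, ")") else "(linear)",
      "\n  method:", object@spec$method,
      " logLik:", signif(object@logLik, 6),
      " AIC:", signif(object@aic, 6),
      " BIC:", signif(object@bic, 6), "\n")
  print(object@fixed, digits = 4)
})
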