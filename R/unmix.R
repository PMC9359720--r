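#' @include AllGenerics.R extinction.R
NULL

#' Restrict a stack to a wavelength window
#'
#' Keeps only the image planes whose wavelength lies in `[lo, hi]`, preserving
#' order. Linear unmixing of two chromophores needs at least two wavelengths,
#' so fewer than two remaining planes is an error.
#'
#' @param stack a [MultispectralStack-class].
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @return The restricted [MultispectralStack-class].
#' @examples
#' st <- simulatePhantom(phantomConfig())$stack
#' wavelengths(selectWavelengths(st, 700, 900))
#' @export
selectWavelengths <- function(stack, lo, hi) {
  stopifnot(is(stack, "MultispectralStack"))
  if (lo >= hi) stop("'lo' must be smaller than 'hi'")
  keep <- which(stack@wavelengths >= lo & stack@wavelengths <= hi)
  if (length(keep) < 2L)
    stop("fewer than 2 wavelengths remain in [", lo, ", ", hi,
         "] nm; unmixing would be underdetermined")
  multispectralStack(stack@pixels[, , keep, drop = FALSE],
                     stack@wavelengths[keep], stack@metadata)
}

# Exact two-component nonnegative least squares for design E (L x 2): try the
# unconstrained solution, else the best single-component or zero fit.
.nnls2 <- function(E, S, W) {
  neg <- which(W[1L, ] < 0 | W[2L, ] < 0)
  if (!length(neg)) return(W)
  for (j in neg) {
    s <- S[, j]
    w1 <- max(0, sum(E[, 1L] * s) / sum(E[, 1L]^2))
    w2 <- max(0, sum(E[, 2L] * s) / sum(E[, 2L]^2))
    r1 <- sum((s - E[, 1L] * w1)^2)
    r2 <- sum((s - E[, 2L] * w2)^2)
    W[, j] <- if (r1 <= r2) c(w1, 0) else c(0, w2)
  }
  W
}

#' Linear spectral unmixing of a multispectral stack
#'
#' Solves, per pixel, the least-squares problem
#' `min_{(hbo2, hb)} sum_lambda (signal(lambda) - eps_HbO2(lambda) * hbo2 -
#' eps_Hb(lambda) * hb)^2` against the extinction spectra interpolated onto
#' the stack's wavelength grid, returning the component weight maps and the
#' per-pixel residual norm. The default solution is unconstrained (weights
#' may be negative, e.g. under noise); `nonnegative = TRUE` switches to the
#' exact two-component nonnegative fit.
#'
#' @param stack a [MultispectralStack-class] with at least 2 wavelengths.
#' @param table an [ExtinctionTable-class] covering the stack's wavelengths.
#' @param nonnegative constrain component weights to be non-negative.
#' @return An [UnmixResult-class].
#' @examples
#' ph <- simulatePhantom(phantomConfig(noise_sd = 0))
#' um <- unmixPixels(selectWavelengths(ph$stack, 700, 900))
#' um
#' @export
unmixPixels <- function(stack, table = hemoglobinExtinction(),
                        nonnegative = FALSE) {
  stopifnot(is(stack, "MultispectralStack"), is(table, "ExtinctionTable"))
  wl <- stack@wavelengths
  if (length(wl) < 2L) stop("at least 2 wavelengths are required for unmixing")
  E <- .interpolateExtinction(table, wl)
  if (qr(E)$rank < 2L)
    stop("extinction matrix is rank-deficient on this wavelength grid ",
         "(collinear HbO2/Hb spectra); unmixing is not identifiable")
  d <- dim(stack@pixels)
  S <- t(matrix(stack@pixels, d[1L] * d[2L], d[3L]))   # L x n_pixels
  W <- solve(crossprod(E), crossprod(E, S))            # 2 x n_pixels
  if (nonnegative) W <- .nnls2(E, S, W)
  res <- sqrt(colSums((S - E %*% W)^2))
  new("UnmixResult",
      hbo2 = matrix(W[1L, ], d[1L], d[2L]),
      hb = matrix(W[2L, ], d[1L], d[2L]),
      residual = matrix(res, d[1L], d[2L]))
}

#' ROI means of unmixed component maps
#'
#' Arithmetic means of the HbO2 and Hb weight maps over the masked pixels.
#' Every pixel inside the mask contributes; none are excluded.
#'
#' @param result an [UnmixResult-class].
#' @param mask a [RoiMask-class] with the same shape.
#' @return list with mean_hbo2, mean_hb, n_pixels.
#' @export
roiStatistics <- function(result, mask) {
  stopifnot(is(result, "UnmixResult"), is(mask, "RoiMask"))
  if (!identical(dim(mask@mask), dim(result@hbo2)))
    stop("mask shape does not match the unmixed maps")
  m <- mask@mask
  if (!any(m)) stop("ROI mask is empty")
  list(mean_hbo2 = mean(result@hbo2[m]), mean_hb = mean(result@hb[m]),
       n_pixels = sum(m))
}

#' Compute an oximetry record from ROI means
#'
#' Turns tumor and reference ROI means into one oximetry record: total
#' hemoglobin `THb = HbO2 + Hb`, apparent oxygen saturation
#' `SO2 = HbO2 / THb` (the ratio of ROI means, not the mean of per-pixel
#' ratios), and reference-normalized THb `THb_tumor / THb_reference`. Under
#' the default clamp policy, negative ROI means are clamped to zero before
#' ratios, which confines SO2 to `[0, 1]`. A tumor THb that is non-positive
#' after clamping flags the record invalid (SO2 is NA, never silently 0); a
#' non-positive reference THb is an error since normalization is impossible.
#'
#' @param mean_hbo2,mean_hb tumor ROI means (a.u.).
#' @param ref_mean_hbo2,ref_mean_hb reference-vessel ROI means (a.u.).
#' @param clamp "negative-to-zero" (default) or "none".
#' @param tumor_id,day optional identifiers carried into the record.
#' @return one-row data.frame: tumor_id, day, mean_hbo2, mean_hb, so2_msot,
#'   thb, ref_thb, thb_normalized, valid.
#' @examples
#' computeOximetry(5, 5, 8, 2)
#' @export
computeOximetry <- function(mean_hbo2, mean_hb, ref_mean_hbo2, ref_mean_hb,
                            clamp = c("negative-to-zero", "none"),
                            tumor_id = NA_character_, day = NA_real_) {
  clamp <- match.arg(clamp)
  v <- c(mean_hbo2, mean_hb, ref_mean_hbo2, ref_mean_hb)
  if (any(!is.finite(v))) stop("ROI means must be finite")
  if (clamp == "negative-to-zero") v <- pmax(v, 0)
  thb <- v[1L] + v[2L]
  ref_thb <- v[3L] + v[4L]
  if (ref_thb <= 0)
    stop("reference THb is not positive after clamping; cannot normalize")
  valid <- thb > 0
  data.frame(tumor_id = tumor_id, day = day,
             mean_hbo2 = v[1L], mean_hb = v[2L],
             so2_msot = if (valid) v[1L] / thb else NA_real_,
             thb = thb, ref_thb = ref_thb,
             thb_normalized = thb / ref_thb, valid = valid,
             stringsAsFactors = FALSE)
}

#' Per-pixel apparent oxygen saturation map
#'
#' Display-oriented per-pixel ratio `HbO2 / (HbO2 + Hb)`. ROI-level oximetry
#' uses the ratio of ROI means instead ([computeOximetry()]); this map is for
#' visualization only.
#'
#' @param result an [UnmixResult-class].
#' @param clamp clamp negative component weights to zero first (default TRUE).
#' @return numeric matrix in `[0, 1]` (NA where total hemoglobin is 0).
#' @export
so2Map <- function(result, clamp = TRUE) {
  stopifnot(is(result, "UnmixResult"))
  hbo2 <- result@hbo2; hb <- result@hb
  if (clamp) { hbo2 <- pmax(hbo2, 0); hb <- pmax(hb, 0) }
  tot <- hbo2 + hb
  out <- hbo2 / tot
  out[tot <= 0] <- NA_real_
  out
}
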