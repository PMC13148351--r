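#' Dose grid accessor
#'
#' @param object a [DoseMap-class] or [MultichannelResult-class]
#' @return numeric matrix of absorbed dose in Gy
#' @export
setGeneric("doseGrid", function(object) standardGeneric("doseGrid"))

#' Pixel spacing accessor
#'
#' @param object a [ScannedFilm-class] or [DoseMap-class]
#' @return numeric length-2 (row, col) spacing in mm
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))

#' Grid origin accessor
#'
#' @param object a [DoseMap-class]
#' @return numeric length-2 (row, col) position of pixel (1,1) center, mm
#' @export
setGeneric("originMm", function(object) standardGeneric("originMm"))

#' Raw pixel array accessor
#'
#' @param object a [ScannedFilm-class]
#' @return numeric array \code{[rows, cols, 3]} of raw scanner counts
#' @export
setGeneric("filmPixels", function(object) standardGeneric("filmPixels"))

#' Bit depth accessor
#'
#' @param object a [ScannedFilm-class]
#' @return integer bits per channel
#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))

#' Model parameter accessor
#'
#' @param object a [CalibrationModel-class]
#' @return named numeric vector of fitted parameters
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' Gamma pass rate
#'
#' Fraction of evaluated reference pixels whose gamma value is at most 1
#' (the inclusive clinical pass convention).
#'
#' @param object a [GammaResult-class]
#' @return numeric in \eqn{[0, 1]}
#' @export
setGeneric("passRate", function(object) standardGeneric("passRate"))

#' t-map accessor
#'
#' @param object a [MultichannelResult-class]
#' @return numeric matrix of per-pixel multichannel scaling factors
#' @export
setGeneric("tMap", function(object) standardGeneric("tMap"))

# -- accessor methods ---------------------------------------------------------

#' @rdname doseGrid
setMethod("doseGrid", "DoseMap", function(object) object@dose)

#' @rdname doseGrid
setMethod("doseGrid", "MultichannelResult", function(object) object@dose@dose)

#' @rdname pixelSpacing
setMethod("pixelSpacing", "DoseMap", function(object) object@pixelSpacing)

#' @rdname pixelSpacing
setMethod("pixelSpacing", "ScannedFilm", function(object) object@pixelSpacing)

#' @rdname originMm
setMethod("originMm", "DoseMap", function(object) object@origin)

#' @rdname filmPixels
setMethod("filmPixels", "ScannedFilm", function(object) object@pixels)

#' @rdname bitDepth
setMethod("bitDepth", "ScannedFilm", function(object) object@bitDepth)

#' @rdname modelParams
setMethod("modelParams", "CalibrationModel", function(object) object@params)

#' @rdname passRate
setMethod("passRate", "GammaResult", function(object) {
  n <- sum(object@evaluated)
  if (n == 0L) stop("no evaluated pixels: pass rate undefined")
  object@passRate
})

#' @rdname tMap
setMethod("tMap", "MultichannelResult", function(object) object@tMap)

# -- show methods -------------------------------------------------------------

setMethod("show", "ScannedFilm", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ScannedFilm: %d x %d px, 3 channels, %d-bit\n", d[1], d[2],
              object@bitDepth))
  cat(sprintf("  pixel spacing: %.4g x %.4g mm\n", object@pixelSpacing[1],
              object@pixelSpacing[2]))
  if (length(object@orientationApplied))
    cat("  orientation applied:", paste(object@orientationApplied, collapse = ", "), "\n")
})

setMethod("show", "DoseMap", function(object) {
  d <- dim(object@dose)
  cat(sprintf("DoseMap: %d x %d px, spacing %.4g x %.4g mm\n",
              d[1], d[2], object@pixelSpacing[1], object@pixelSpacing[2]))
  cat(sprintf("  dose range: [%.4g, %.4g] Gy, origin (%.4g, %.4g) mm\n",
              min(object@dose), max(object@dose), object@origin[1], object@origin[2]))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel (%s, channel %s, response %s)\n",
              object@modelKind, object@channel, object@responseKind))
  p <- paste(sprintf("%s = %.6g", names(object@params), object@params),
             collapse = ", ")
  cat("  params:", p, "\n")
  cat(sprintf("  dose range: [%g, %g] Gy\n", object@doseRange[1], object@doseRange[2]))
  if (!is.null(object@gof$rSquared))
    cat(sprintf("  R^2 = %.6f, reduced chi^2 = %.4g\n",
                object@gof$rSquared, object@gof$redChiSq))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: offset (%d, %d) px, angle %.2f deg, NCC %.5f\n",
              object@offsetPx[1], object@offsetPx[2], object@angleDeg,
              object@nccScore))
})

setMethod("show", "GammaCriteria", function(object) {
  unit <- if (object@normalization == "absolute") "Gy" else "%"
  cat(sprintf("GammaCriteria: %g%s / %g mm, threshold %g%%, %s normalization\n",
              object@ddPercent, unit, object@dtaMm, object@thresholdPercent,
              object@normalization))
})

setMethod("show", "GammaResult", function(object) {
  n <- sum(object@evaluated)
  cat(sprintf("GammaResult: %d evaluated pixels, pass rate %.2f%%\n",
              n, 100 * object@passRate))
  show(object@criteria)
})

setMethod("show", "MultichannelResult", function(object) {
  nc <- sum(!object@converged)
  cat("MultichannelResult\n")
  show(object@dose)
  cat(sprintf("  t-map range: [%.5f, %.5f]; %d non-converged pixel(s)\n",
              min(object@tMap), max(object@tMap), nc))
})
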