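#' @import methods
NULL

#' ScannedFilm: a digitized radiochromic film
#'
#' Container for a raw flatbed-scanner acquisition of a radiochromic film:
#' an integer RGB pixel grid together with its bit depth and physical pixel
#' spacing. Pixel values ("PV") are raw scanner counts in
#' \eqn{[0, 2^{bits}-1]}; no rescaling is applied on read.
#'
#' Geometry convention: matrices are indexed \code{[row, col]} with row 1 at
#' the top of the scan (scanner convention, rows increase downward). The
#' physical center of pixel \code{(i, j)} is at
#' \code{origin + (i-1, j-1) * pixelSpacing} millimetres.
#'
#' @slot pixels numeric array \code{[rows, cols, 3]} of integer-valued counts,
#'   channels ordered red, green, blue.
#' @slot bitDepth integer, bits per channel (8 or 16 for scanner data).
#' @slot pixelSpacing numeric length-2, (row, col) spacing in mm; both > 0.
#' @slot orientationApplied character vector naming pre-processing transforms
#'   already applied (e.g. \code{"flip_vertical"}, \code{"rotate_180"}).
#' @slot metadata list of provenance details (dpi, source path, synthetic
#'   ground truth for generated films).
#'
#' @seealso [readTiffFilm()], [filmFromDose()], [roiStatistics()]
#' @export
setClass("ScannedFilm",
  representation(
    pixels = "array",
    bitDepth = "integer",
    pixelSpacing = "numeric",
    orientationApplied = "character",
    metadata = "list"
  ),
  prototype(
    orientationApplied = character(0),
    metadata = list()
  )
)

setValidity("ScannedFilm", function(object) {
  msg <- character(0)
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "pixels must be a rows x cols x 3 array (red, green, blue)")
  if (length(object@bitDepth) != 1L || is.na(object@bitDepth) ||
      object@bitDepth < 1L || object@bitDepth > 16L)
    msg <- c(msg, "bitDepth must be a single integer in [1, 16]")
  else if (length(d) == 3L) {
    pvmax <- 2^object@bitDepth - 1
    rng <- range(object@pixels)
    if (anyNA(object@pixels) || rng[1] < 0 || rng[2] > pvmax)
      msg <- c(msg, sprintf("pixel values must lie in [0, %d]", pvmax))
  }
  if (length(object@pixelSpacing) != 2L || any(!is.finite(object@pixelSpacing)) ||
      any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive values (row, col) in mm")
  if (length(msg)) msg else TRUE
})

#' DoseMap: a 2-D absorbed-dose grid
#'
#' The planar dose distribution exchanged with DICOM RT Dose: a matrix of
#' absorbed dose in gray (Gy) with physical pixel spacing and the position of
#' the first pixel's center. Same geometry convention as [ScannedFilm-class].
#'
#' @slot dose numeric matrix of absorbed dose (Gy), finite and non-negative.
#' @slot pixelSpacing numeric length-2, (row, col) spacing in mm; both > 0.
#' @slot origin numeric length-2, physical (row, col) position in mm of the
#'   center of pixel (1, 1).
#'
#' @seealso [readRTDose()], [writeRTDose()], [resampleToGrid()]
#' @export
setClass("DoseMap",
  representation(
    dose = "matrix",
    pixelSpacing = "numeric",
    origin = "numeric"
  ),
  prototype(origin = c(0, 0))
)

setValidity("DoseMap", function(object) {
  msg <- character(0)
  if (!is.numeric(object@dose) || length(object@dose) == 0L)
    msg <- c(msg, "dose must be a non-empty numeric matrix")
  else if (any(!is.finite(object@dose)))
    msg <- c(msg, "dose must be finite everywhere")
  else if (any(object@dose < 0))
    msg <- c(msg, "dose must be non-negative (Gy)")
  if (length(object@pixelSpacing) != 2L || any(!is.finite(object@pixelSpacing)) ||
      any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive values (row, col) in mm")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite values (row, col) in mm")
  if (length(msg)) msg else TRUE
})

#' CalibrationModel: a fitted per-channel dose-response law
#'
#' Holds the parameters, approximate parameter uncertainties and fit
#' diagnostics of one channel's calibration function. Two model families are
#' supported, matching common radiochromic-film practice:
#' \describe{
#'   \item{rational}{\eqn{D = A\,netT / (1 - B\,netT)}, a function of the net
#'     transmittance change (response kind \code{"net_t"}).}
#'   \item{polynomial}{\eqn{D = A\,netOD + B\,netOD^{n}}, a function of the
#'     net optical-density change (response kind \code{"net_od"}).}
#' }
#'
#' @slot modelKind \code{"rational"} or \code{"polynomial"}.
#' @slot channel \code{"R"}, \code{"G"} or \code{"B"}.
#' @slot params named numeric: \code{A, B} (rational) or \code{A, B, n}
#'   (polynomial).
#' @slot paramSigma named numeric, approximate 1-sigma parameter
#'   uncertainties from the fit Jacobian (zero for exact/constructed models).
#' @slot responseKind \code{"net_t"} or \code{"net_od"}.
#' @slot doseRange numeric length-2, calibrated dose range in Gy.
#' @slot gof list of goodness-of-fit diagnostics (\code{redChiSq},
#'   \code{rSquared}, \code{nPoints}, \code{converged}).
#'
#' @seealso [fitCalibration()], [predictDose()], [invertDose()]
#' @export
setClass("CalibrationModel",
  representation(
    modelKind = "character",
    channel = "character",
    params = "numeric",
    paramSigma = "numeric",
    responseKind = "character",
    doseRange = "numeric",
    gof = "list"
  ),
  prototype(gof = list())
)

setValidity("CalibrationModel", function(object) {
  msg <- character(0)
  if (!object@modelKind %in% c("rational", "polynomial"))
    msg <- c(msg, "modelKind must be 'rational' or 'polynomial'")
  if (!object@channel %in% c("R", "G", "B"))
    msg <- c(msg, "channel must be 'R', 'G' or 'B'")
  np <- if (identical(object@modelKind, "rational")) 2L else 3L
  if (length(object@params) != np)
    msg <- c(msg, sprintf("%s model must have exactly %d parameters",
                          object@modelKind, np))
  if (!object@responseKind %in% c("net_t", "net_od"))
    msg <- c(msg, "responseKind must be 'net_t' or 'net_od'")
  if (length(object@doseRange) != 2L || object@doseRange[1] >= object@doseRange[2])
    msg <- c(msg, "doseRange must be an increasing pair of doses (Gy)")
  if (length(msg)) msg else TRUE
})

#' RegistrationResult: location of the plan inside the film
#'
#' Result of normalized cross-correlation template matching: the (row, col)
#' of the matched region's top-left pixel in the film grid (1-based), the
#' template rotation that maximised the score, the peak NCC value, and the
#' full score map at the winning angle.
#'
#' @slot offsetPx integer length-2, 1-based (row, col) of the matched
#'   region's top-left pixel.
#' @slot angleDeg numeric, template rotation applied (degrees).
#' @slot nccScore numeric in \eqn{[-1, 1]}, the peak normalized
#'   cross-correlation.
#' @slot scoreMap numeric matrix of NCC over all valid placements at the
#'   winning angle.
#' @slot anglesTried numeric, the rotation sweep evaluated.
#'
#' @seealso [matchTemplate()], [cropMatched()]
#' @export
setClass("RegistrationResult",
  representation(
    offsetPx = "integer",
    angleDeg = "numeric",
    nccScore = "numeric",
    scoreMap = "matrix",
    anglesTried = "numeric"
  )
)

setValidity("RegistrationResult", function(object) {
  msg <- character(0)
  if (length(object@offsetPx) != 2L || any(object@offsetPx < 1L))
    msg <- c(msg, "offsetPx must be two 1-based indices")
  if (abs(object@nccScore) > 1 + 1e-9)
    msg <- c(msg, "nccScore must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' GammaCriteria: parameters of the gamma-index test
#'
#' @slot ddPercent dose-difference criterion; percent of the normalization
#'   dose in \code{"global"}/\code{"local"} modes, absolute Gy in
#'   \code{"absolute"} mode.
#' @slot dtaMm distance-to-agreement criterion in mm.
#' @slot thresholdPercent reference pixels below this percent of the
#'   reference maximum are excluded from evaluation.
#' @slot normalization \code{"global"} (percent of the reference maximum),
#'   \code{"local"} (percent of each reference pixel's dose) or
#'   \code{"absolute"} (Gy).
#' @slot searchRadiusFactor spatial search cutoff as a multiple of the DTA.
#'
#' @seealso [gammaCriteria()], [gammaMatrix()]
#' @export
setClass("GammaCriteria",
  representation(
    ddPercent = "numeric",
    dtaMm = "numeric",
    thresholdPercent = "numeric",
    normalization = "character",
    searchRadiusFactor = "numeric"
  )
)

setValidity("GammaCriteria", function(object) {
  msg <- character(0)
  if (object@ddPercent <= 0) msg <- c(msg, "ddPercent must be > 0")
  if (object@dtaMm <= 0) msg <- c(msg, "dtaMm must be > 0")
  if (object@thresholdPercent < 0) msg <- c(msg, "thresholdPercent must be >= 0")
  if (!object@normalization %in% c("global", "local", "absolute"))
    msg <- c(msg, "normalization must be 'global', 'local' or 'absolute'")
  if (object@searchRadiusFactor <= 0)
    msg <- c(msg, "searchRadiusFactor must be > 0")
  if (length(msg)) msg else TRUE
})

#' GammaResult: per-pixel gamma matrix and pass statistics
#'
#' @slot gamma numeric matrix of gamma values aligned to the reference map
#'   (NA where not evaluated).
#' @slot evaluated logical matrix, TRUE where the reference pixel entered the
#'   statistics.
#' @slot passRate fraction of evaluated pixels with gamma <= 1.
#' @slot criteria the [GammaCriteria-class] used.
#'
#' @seealso [gammaMatrix()], [passRate()], [gammaHistogram()]
#' @export
setClass("GammaResult",
  representation(
    gamma = "matrix",
    evaluated = "matrix",
    passRate = "numeric",
    criteria = "GammaCriteria"
  )
)

setValidity("GammaResult", function(object) {
  msg <- character(0)
  if (!identical(dim(object@gamma), dim(object@evaluated)))
    msg <- c(msg, "gamma and evaluated must have identical dimensions")
  g <- object@gamma[object@evaluated]
  if (length(g) && (anyNA(g) || any(g < 0)))
    msg <- c(msg, "gamma must be >= 0 on evaluated pixels")
  if (length(msg)) msg else TRUE
})

#' MultichannelResult: multichannel dose reconstruction output
#'
#' Output of the disturbance-separating multichannel method: the averaged
#' dose map, the per-pixel scaling factor t (the "t-map" of dose-independent
#' non-homogeneities), iteration counts, and a convergence flag per pixel.
#' Non-converged pixels are flagged and filled with the red-channel
#' single-channel dose, never left as holes.
#'
#' @slot dose a [DoseMap-class], mean of the three channel doses at t_min.
#' @slot tMap numeric matrix of per-pixel scaling factors (positive where
#'   converged).
#' @slot iterations integer matrix of Newton iteration counts.
#' @slot converged logical matrix.
#'
#' @seealso [multichannelDose()]
#' @export
setClass("MultichannelResult",
  representation(
    dose = "DoseMap",
    tMap = "matrix",
    iterations = "matrix",
    converged = "matrix"
  )
)

setValidity("MultichannelResult", function(object) {
  msg <- character(0)
  if (!identical(dim(object@tMap), dim(object@dose@dose)))
    msg <- c(msg, "tMap must match the dose grid dimensions")
  tm <- object@tMap[object@converged]
  if (length(tm) && any(tm <= 0))
    msg <- c(msg, "tMap must be positive where converged")
  if (length(msg)) msg else TRUE
})
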