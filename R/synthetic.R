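# Synthetic phantoms, films and registration cases: a fully specified
# generative stand-in for physical film irradiation and scanning, so every
# pipeline stage is testable without hardware. All generators are
# bit-reproducible given (spec, seed).

#' Synthetic calibration ground truth
#'
#' Three channel-distinct rational calibration models used as the fixture
#' truth throughout the synthetic pipeline. The red channel has the steepest
#' response at low dose (the largest \eqn{|dD/dnetT|^{-1}} sensitivity),
#' mirroring the stronger color change of real radiochromic film in the red
#' part of the spectrum; green and blue are progressively less sensitive.
#' The exact values are fixture constants chosen so every channel's net
#' transmittance stays inside \eqn{(-1, 0]} up to 10 Gy.
#'
#' @param doseRange calibrated dose range in Gy
#' @return named list of three [CalibrationModel-class] (R, G, B)
#' @export
syntheticCalibrationModels <- function(doseRange = c(0, 10)) {
  truth <- list(R = c(A = -20, B = 0.5),
                G = c(A = -30, B = 0.4),
                B = c(A = -50, B = 0.3))
  models <- lapply(names(truth), function(ch)
    new("CalibrationModel", modelKind = "rational", channel = ch,
        params = truth[[ch]],
        paramSigma = c(A = 0, B = 0),
        responseKind = "net_t", doseRange = as.numeric(doseRange),
        gof = list(redChiSq = 0, rSquared = 1, nPoints = 0L,
                   converged = TRUE)))
  names(models) <- names(truth)
  models
}

#' Scanner noise specification
#'
#' Generative model of the scanner artifacts seen in real film digitization:
#' additive Gaussian pixel-value noise, isolated salt spikes (dust and
#' non-functional sensor pixels), and a smooth multiplicative dose-independent
#' disturbance of the optical density (areas of reduced pixel sensitivity) —
#' exactly the structure the multichannel method is designed to separate.
#'
#' @param gaussianSigmaFraction Gaussian PV noise sigma as a fraction of the
#'   pixel value
#' @param spikeProbability per-pixel probability of a full-scale salt spike
#' @param disturbanceAmplitude peak deviation of the smooth multiplicative
#'   OD field from 1
#' @param seed integer RNG seed; equal seeds give bit-identical films
#' @return a list with class \code{"ScannerNoiseSpec"}
#' @export
scannerNoiseSpec <- function(gaussianSigmaFraction = 0, spikeProbability = 0,
                             disturbanceAmplitude = 0, seed = 1L) {
  stopIfNot(spikeProbability >= 0 && spikeProbability <= 1,
            "spikeProbability must be in [0, 1]")
  stopIfNot(gaussianSigmaFraction >= 0 && disturbanceAmplitude >= 0,
            "noise amplitudes must be >= 0")
  structure(list(gaussianSigmaFraction = gaussianSigmaFraction,
                 spikeProbability = spikeProbability,
                 disturbanceAmplitude = disturbanceAmplitude,
                 seed = as.integer(seed)),
            class = "ScannerNoiseSpec")
}

logisticEdge <- function(x, halfWidth, scale) {
  stats::plogis((halfWidth - abs(x)) / scale)
}

#' Generate a planned dose phantom
#'
#' Deterministic analytic dose distributions emulating the validation
#' fields of a film QA commissioning:
#' \describe{
#'   \item{uniform_square}{\eqn{D(x, y) = D_0 S(x) S(y)} with S a logistic
#'     edge profile of scale \code{penumbraSigmaMm} — a flat field with a
#'     smooth penumbra.}
#'   \item{pyramid}{a stack of nested concentric squares; level k adds
#'     \eqn{(D_k - D_{k-1})} inside a square of side
#'     \code{fieldSizeMm * (n-k+1)/n}, each edge smoothed by the same
#'     logistic profile. The center pixel reaches the last listed dose.}
#' }
#'
#' @param kind \code{"uniform_square"} or \code{"pyramid"}
#' @param doseGy plateau dose (uniform_square) or increasing level doses
#'   (pyramid), Gy; all levels within the 0.5-20 Gy applicability range
#' @param fieldSizeMm field side length, within 50-220 mm
#' @param penumbraSigmaMm logistic edge scale in mm
#' @param gridSpacingMm pixel spacing of the generated grid
#' @param marginMm background margin around the field on every side
#' @return a [DoseMap-class]
#' @export
makeDosePhantom <- function(kind = c("uniform_square", "pyramid"),
                            doseGy = 5, fieldSizeMm = 100,
                            penumbraSigmaMm = 2, gridSpacingMm = 1,
                            marginMm = 20) {
  kind <- match.arg(kind)
  stopIfNot(all(doseGy >= 0.5 & doseGy <= 20),
            "doses must lie within the 0.5-20 Gy applicability range")
  stopIfNot(fieldSizeMm >= 50 && fieldSizeMm <= 220,
            "field size must lie within 50-220 mm")
  stopIfNot(gridSpacingMm > 0 && penumbraSigmaMm > 0, "spacings must be > 0")
  extent <- fieldSizeMm + 2 * marginMm
  n <- max(2L, as.integer(round(extent / gridSpacingMm)))
  pos <- (seq_len(n) - (n + 1) / 2) * gridSpacingMm  # centered coordinates
  X <- matrix(pos, n, n, byrow = TRUE)
  Y <- matrix(pos, n, n)
  if (kind == "uniform_square") {
    stopIfNot(length(doseGy) == 1L, "uniform_square takes a single dose")
    d <- doseGy * logisticEdge(X, fieldSizeMm / 2, penumbraSigmaMm) *
      logisticEdge(Y, fieldSizeMm / 2, penumbraSigmaMm)
  } else {
    stopIfNot(length(doseGy) >= 2L && all(diff(doseGy) > 0),
              "pyramid takes increasing level doses")
    nl <- length(doseGy)
    inc <- diff(c(0, doseGy))
    d <- matrix(0, n, n)
    for (k in seq_len(nl)) {
      half <- fieldSizeMm * (nl - k + 1) / nl / 2
      d <- d + inc[k] * logisticEdge(X, half, penumbraSigmaMm) *
        logisticEdge(Y, half, penumbraSigmaMm)
    }
  }
  DoseMap(d, pixelSpacing = gridSpacingMm, origin = c(0, 0))
}

# Smooth quadratic disturbance surface with peak |deviation| = amplitude,
# coefficients drawn from the (already seeded) RNG stream.
disturbanceField <- function(nr, nc, amplitude) {
  if (amplitude == 0) return(matrix(1, nr, nc))
  x <- seq(-1, 1, length.out = nc)
  y <- seq(-1, 1, length.out = nr)
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  cf <- stats::runif(5, -1, 1)
  q <- cf[1] * X^2 + cf[2] * X * Y + cf[3] * Y^2 + cf[4] * X + cf[5] * Y
  q <- q / max(abs(q))
  1 + amplitude * q
}

#' Generate a synthetic scanned film from a dose map
#'
#' The forward model of film irradiation plus flatbed scanning. Per channel:
#' the calibration inverse maps dose to net transmittance, the implied
#' optical density is multiplied by a smooth quadratic disturbance field
#' (the dose-independent non-homogeneity the multichannel method separates),
#' and the pixel value is the transmittance on the 16-bit scale with
#' additive Gaussian noise and salt spikes, rounded half-even to integer
#' counts. Optionally the film is embedded into a larger unexposed canvas at
#' a known offset and rotation — the ground truth for registration tests.
#'
#' All randomness derives from \code{noise$seed}; the injected disturbance
#' field and embedding truth are stored in the film's \code{metadata}
#' (\code{disturbance}, and \code{tTruth} = its reciprocal, the scaling the
#' multichannel method should recover).
#'
#' @param dose a [DoseMap-class] within each model's calibrated range
#' @param models three [CalibrationModel-class] (R, G, B), monotone
#' @param noise a [scannerNoiseSpec()]
#' @param embed optional list \code{(canvasPx, offsetPx, angleDeg)}:
#'   canvas size (rows, cols), 1-based top-left paste position, rotation
#' @return a [ScannedFilm-class] with generation truth in \code{metadata}
#' @export
filmFromDose <- function(dose, models = syntheticCalibrationModels(),
                         noise = scannerNoiseSpec(), embed = NULL) {
  stopIfNot(inherits(noise, "ScannerNoiseSpec"), "noise must be a scannerNoiseSpec()")
  if (!is.null(names(models)) && all(c("R", "G", "B") %in% names(models)))
    models <- models[c("R", "G", "B")]
  rngmax <- vapply(models, function(m) m@doseRange[2], numeric(1))
  if (max(dose@dose) > min(rngmax) + 1e-9)
    stop("dose exceeds the calibrated range of at least one channel model",
         call. = FALSE)
  d <- dim(dose@dose)
  withSeed(noise$seed, {
    pert <- disturbanceField(d[1], d[2], noise$disturbanceAmplitude)
    ods <- lapply(1:3, function(k) {
      m <- models[[k]]
      r <- responseAtDose(m, as.vector(dose@dose))
      od <- if (m@responseKind == "net_t") -log10(pmax(1 + r, 1e-9))
            else pmax(r, 0)
      matrix(od, d[1], d[2]) * pert
    })
    if (!is.null(embed)) {
      canvas <- embed$canvasPx
      off <- embed$offsetPx
      ang <- if (is.null(embed$angleDeg)) 0 else embed$angleDeg
      stopIfNot(all(off >= 1) && off[1] + d[1] - 1 <= canvas[1] &&
                  off[2] + d[2] - 1 <= canvas[2],
                "embedding exceeds the canvas")
      ods <- lapply(ods, function(od) {
        if (ang != 0) od <- pmax(rotateBilinear(od, ang, fill = 0), 0)
        cv <- matrix(0, canvas[1], canvas[2])
        cv[off[1]:(off[1] + d[1] - 1L), off[2]:(off[2] + d[2] - 1L)] <- od
        cv
      })
      d <- canvas
    }
    pvmax <- 65535
    pixels <- array(0, c(d[1], d[2], 3L))
    for (k in 1:3) {
      pv <- pvmax * 10^(-ods[[k]])
      if (noise$gaussianSigmaFraction > 0)
        pv <- pv + stats::rnorm(length(pv), 0, noise$gaussianSigmaFraction * pv)
      pv <- round(pv)  # round-half-even, deterministic across platforms
      if (noise$spikeProbability > 0) {
        spikes <- stats::runif(length(pv)) < noise$spikeProbability
        pv[spikes] <- pvmax
      }
      pixels[, , k] <- pmin(pmax(matrix(pv, d[1], d[2]), 0), pvmax)
    }
    ScannedFilm(pixels, bitDepth = 16L, pixelSpacing = dose@pixelSpacing,
                metadata = list(synthetic = TRUE, seed = noise$seed,
                                disturbance = pert, tTruth = 1 / pert,
                                embed = embed))
  })
}

#' Generate a registration test case with known ground truth
#'
#' Embeds a planned dose distribution into a larger unexposed film canvas at
#' a known (offset, angle), runs the forward scanner model, and returns both
#' the film and the ground-truth record.
#'
#' @param plan a [DoseMap-class]
#' @param offsetPx integer (row, col), 1-based top-left paste position
#' @param angleDeg rotation applied to the embedded plan
#' @param noise a [scannerNoiseSpec()]
#' @param canvasPx integer (rows, cols) canvas size
#' @param models calibration truth used by the forward model
#' @return list with \code{film} ([ScannedFilm-class]) and \code{truth}
#'   (list \code{offsetPx}, \code{angleDeg})
#' @export
makeRegistrationCase <- function(plan, offsetPx, angleDeg = 0,
                                 noise = scannerNoiseSpec(),
                                 canvasPx = dim(plan@dose) + 60L,
                                 models = syntheticCalibrationModels()) {
  film <- filmFromDose(plan, models = models, noise = noise,
                       embed = list(canvasPx = as.integer(canvasPx),
                                    offsetPx = as.integer(offsetPx),
                                    angleDeg = angleDeg))
  list(film = film,
       truth = list(offsetPx = as.integer(offsetPx), angleDeg = angleDeg))
}
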