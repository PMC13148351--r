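# Film response extraction: pixel values -> transmittance / optical density,
# ROI statistics, net responses with propagated uncertainties, denoising.

#' Pixel value to transmittance
#'
#' Per-pixel transmittance is estimated as \eqn{T = PV / (2^{bits} - 1)},
#' the measured count as a fraction of the full scanner scale.
#'
#' @param pv pixel value(s), counts in \eqn{[0, 2^{bits}-1]}
#' @param bitDepth bits per channel
#' @return transmittance, dimensionless in \eqn{[0, 1]}
#' @examples
#' pixelToTransmittance(65535, 16)  # 1
#' pixelToTransmittance(32768, 16)  # 0.5000076...
#' @export
pixelToTransmittance <- function(pv, bitDepth) {
  pvmax <- 2^bitDepth - 1
  if (any(pv < 0 | pv > pvmax))
    stop(sprintf("pixel value out of range [0, %d]", pvmax), call. = FALSE)
  pv / pvmax
}

#' Transmittance to optical density
#'
#' \eqn{OD = -\log_{10} T}. A transmittance of exactly zero (dead pixel,
#' PV = 0) is clamped to one count above zero before the logarithm so that
#' dead pixels surface as extreme-but-finite OD rather than infinities.
#'
#' @param t transmittance value(s) in \eqn{[0, 1]}
#' @param bitDepth bits per channel, used only for the zero clamp
#' @return optical density, dimensionless
#' @export
transmittanceToOD <- function(t, bitDepth = 16L) {
  tmin <- 1 / (2^bitDepth - 1)
  -log10(pmax(t, tmin))
}

#' Optical density to transmittance
#'
#' @param od optical density value(s)
#' @return transmittance \eqn{10^{-OD}}
#' @export
odToTransmittance <- function(od) 10^(-od)

#' Per-channel ROI statistics of a scanned film
#'
#' Mean and standard deviation of the raw pixel values over a rectangular
#' region of interest, computed per channel. The standard deviation is the
#' population form (divide by n): film ROIs contain thousands of pixels and
#' the fixed convention keeps the uncertainty chain exactly reproducible.
#'
#' @param film a [ScannedFilm-class]
#' @param roi integer length-4 \code{c(row0, col0, height, width)}, 1-based
#'   top-left corner plus extent in pixels
#' @return list with \code{meanPv}, \code{sdPv} (named numeric length-3,
#'   channels R/G/B) and \code{nPixels}
#' @export
roiStatistics <- function(film, roi) {
  stopIfNot(length(roi) == 4L && all(roi >= 1), "roi must be (row0, col0, height, width), all >= 1")
  d <- dim(film@pixels)
  r <- roi[1]:(roi[1] + roi[3] - 1L)
  cl <- roi[2]:(roi[2] + roi[4] - 1L)
  if (max(r) > d[1] || max(cl) > d[2])
    stop("roi exceeds image bounds", call. = FALSE)
  chans <- c("R", "G", "B")
  meanPv <- sdPv <- setNames(numeric(3), chans)
  n <- length(r) * length(cl)
  for (k in 1:3) {
    v <- film@pixels[r, cl, k]
    meanPv[k] <- mean(v)
    sdPv[k] <- sqrt(sum((v - meanPv[k])^2) / n)  # population sd
  }
  list(meanPv = meanPv, sdPv = sdPv, nPixels = n)
}

#' Net film response with propagated uncertainty
#'
#' Channel-wise net transmittance and net optical density between a
#' pre-irradiation ("i") and post-irradiation ("f") measurement:
#' \deqn{netT = T_f - T_i, \qquad netOD = OD_f - OD_i,}
#' with the netOD uncertainty propagated from the ROI pixel-value scatter as
#' \deqn{\sigma_{netOD} = \frac{1}{\ln 10}\sqrt{(\sigma_{PV_f}/PV_f)^2 +
#'   (\sigma_{PV_i}/PV_i)^2}.}
#' The net transmittance keeps its literal sign (negative for a darkening
#' film); the calibration parameters absorb the sign.
#'
#' @param pre,post ROI statistics from [roiStatistics()] for the
#'   pre-irradiation and post-irradiation scans
#' @param bitDepth bits per channel
#' @return data.frame with one row per channel: \code{channel}, \code{netT},
#'   \code{netOD}, \code{sigmaNetOD}, \code{sigmaNetT}
#' @export
netResponse <- function(pre, post, bitDepth = 16L) {
  if (any(pre$meanPv <= 0) || any(post$meanPv <= 0))
    stop("zero mean pixel value: optical density undefined", call. = FALSE)
  pvmax <- 2^bitDepth - 1
  ti <- pre$meanPv / pvmax
  tf <- post$meanPv / pvmax
  netT <- tf - ti
  netOD <- -log10(tf) + log10(ti)
  sigmaNetOD <- (1 / log(10)) *
    sqrt((post$sdPv / post$meanPv)^2 + (pre$sdPv / pre$meanPv)^2)
  sigmaNetT <- sqrt((post$sdPv / pvmax)^2 + (pre$sdPv / pvmax)^2)
  data.frame(channel = c("R", "G", "B"), netT = unname(netT),
             netOD = unname(netOD), sigmaNetOD = unname(sigmaNetOD),
             sigmaNetT = unname(sigmaNetT), stringsAsFactors = FALSE)
}

#' Inverse-variance weighted net response
#'
#' Combines replicate net optical-density (or net transmittance)
#' measurements into the minimum-variance weighted average
#' \deqn{\overline{netOD} = \sum_i \omega_i\, netOD_i, \qquad
#'   \omega_i = \frac{1/\sigma_i^2}{\sum_j 1/\sigma_j^2},}
#' with total uncertainty \eqn{\sigma = \sqrt{1 / \sum_i \sigma_i^{-2}}}.
#' With equal sigmas this is the arithmetic mean and the uncertainty shrinks
#' by \eqn{\sqrt{N}}. If every sigma is zero the equal-weight mean is
#' returned with zero uncertainty; mixing zero and non-zero sigmas is
#' ill-posed and raises an error.
#'
#' @param values numeric vector of replicate responses
#' @param sigma numeric vector of their uncertainties (same length)
#' @return named numeric: \code{mean}, \code{sigma}
#' @export
weightedNetOD <- function(values, sigma) {
  stopIfNot(length(values) >= 1L, "need at least one measurement")
  stopIfNot(length(values) == length(sigma), "values and sigma lengths differ")
  if (all(sigma == 0)) return(c(mean = mean(values), sigma = 0))
  if (any(sigma == 0))
    stop("mixed zero and non-zero sigmas: weights ill-posed", call. = FALSE)
  w <- 1 / sigma^2
  c(mean = sum(w * values) / sum(w), sigma = sqrt(1 / sum(w)))
}

# 2-D median filter with replicate padding; exact spike removal.
medianFilter2D <- function(x, size) {
  if (size == 1L) return(x)
  k <- (size - 1L) %/% 2L
  p <- padReplicate(x, k)
  nr <- nrow(x); nc <- ncol(x)
  stack <- array(NA_real_, c(nr, nc, size * size))
  s <- 1L
  for (dr in 0:(size - 1L)) for (dc in 0:(size - 1L)) {
    stack[, , s] <- p[dr + seq_len(nr), dc + seq_len(nc)]
    s <- s + 1L
  }
  apply(stack, c(1L, 2L), median)
}

# Locally adaptive Wiener filter: local-mean/local-variance shrinkage with
# the noise power estimated as the mean of the local variances.
wienerFilter2D <- function(x, size) {
  if (size == 1L) return(x)
  n <- size * size
  m <- localSum(x, size) / n
  v <- pmax(localSum(x^2, size) / n - m^2, 0)
  noise <- mean(v)
  gain <- ifelse(v > 0, pmax(v - noise, 0) / v, 0)
  m + gain * (x - m)
}

#' Denoise a scanner image
#'
#' Two-stage scanner-noise reduction: a median filter removes isolated
#' salt spikes (dust, defective pixels), then a locally adaptive Wiener
#' filter shrinks each pixel toward its local mean in proportion to how much
#' the local variance exceeds the estimated noise power (the mean of the
#' local variances over the image). A window size of 1 disables a stage.
#' Constant images pass through unchanged; the output shape always equals
#' the input shape.
#'
#' @param image numeric matrix
#' @param medianSize odd integer, median window (1 disables)
#' @param wienerWindow odd integer, Wiener window (1 disables)
#' @return numeric matrix, same shape
#' @export
denoiseImage <- function(image, medianSize = 3L, wienerWindow = 5L) {
  stopIfNot(medianSize >= 1L && medianSize %% 2L == 1L,
            "medianSize must be an odd integer >= 1")
  stopIfNot(wienerWindow >= 1L && wienerWindow %% 2L == 1L,
            "wienerWindow must be an odd integer >= 1")
  wienerFilter2D(medianFilter2D(image, as.integer(medianSize)),
                 as.integer(wienerWindow))
}
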