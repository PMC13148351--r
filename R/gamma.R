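# Gamma-index comparison of planned and measured dose maps with DTA / DD
# criteria, normalization modes, low-dose threshold, pass rate, histogram.

#' Construct gamma-test criteria
#'
#' @param ddPercent dose-difference criterion (percent of the normalization
#'   dose; absolute Gy when \code{normalization = "absolute"})
#' @param dtaMm distance-to-agreement criterion in mm
#' @param thresholdPercent exclude reference pixels below this percent of
#'   the reference maximum
#' @param normalization \code{"global"}, \code{"local"} or \code{"absolute"}
#' @param searchRadiusFactor spatial search cutoff as a multiple of the DTA
#' @return a [GammaCriteria-class]
#' @examples
#' gammaCriteria(3, 3, 5, "global")  # the standard clinical 3%/3 mm test
#' @export
gammaCriteria <- function(ddPercent = 3, dtaMm = 3, thresholdPercent = 5,
                          normalization = c("global", "local", "absolute"),
                          searchRadiusFactor = 3) {
  new("GammaCriteria", ddPercent = ddPercent, dtaMm = dtaMm,
      thresholdPercent = thresholdPercent,
      normalization = match.arg(normalization),
      searchRadiusFactor = searchRadiusFactor)
}

# Sample `measured` on the reference grid (bilinear); returns the matrix
# plus a mask of reference pixels whose centers fall inside the measured
# extent.
measuredOnReferenceGrid <- function(reference, measured) {
  if (identical(dim(reference@dose), dim(measured@dose)) &&
      isTRUE(all.equal(reference@pixelSpacing, measured@pixelSpacing)) &&
      isTRUE(all.equal(reference@origin, measured@origin)))
    return(list(dose = measured@dose,
                inside = matrix(TRUE, nrow(measured@dose), ncol(measured@dose))))
  d <- dim(reference@dose)
  rPos <- reference@origin[1] + (seq_len(d[1]) - 1) * reference@pixelSpacing[1]
  cPos <- reference@origin[2] + (seq_len(d[2]) - 1) * reference@pixelSpacing[2]
  ri <- (rPos - measured@origin[1]) / measured@pixelSpacing[1] + 1
  ci <- (cPos - measured@origin[2]) / measured@pixelSpacing[2] + 1
  dm <- dim(measured@dose)
  insideR <- ri >= 1 - 1e-9 & ri <= dm[1] + 1e-9
  insideC <- ci >= 1 - 1e-9 & ci <= dm[2] + 1e-9
  if (!any(insideR) || !any(insideC))
    stop("reference and measured grids do not overlap", call. = FALSE)
  rc <- matrix(ri, d[1], d[2])
  cc <- matrix(ci, d[1], d[2], byrow = TRUE)
  v <- bilinearSample(measured@dose, as.vector(rc), as.vector(cc), clamp = TRUE)
  list(dose = matrix(v, d[1], d[2]),
       inside = outer(insideR, insideC, `&`))
}

#' Gamma-index matrix between a reference and a measured dose map
#'
#' For each reference pixel above the dose threshold, computes
#' \deqn{\gamma(\vec r_c) = \min_{\vec r_m} \sqrt{\frac{|\vec r_c - \vec r_m|^2}
#'   {DTA^2} + \frac{(D_{ref}(\vec r_c) - D_{meas}(\vec r_m))^2}
#'   {\Delta D^2}},}
#' the minimum over measured pixels within the search radius
#' (\code{searchRadiusFactor} times the DTA; the zero-displacement candidate
#' is always included, so no pixel is ever left without a candidate).
#' The dose-difference denominator \eqn{\Delta D} depends on the
#' normalization mode: \code{dd\%} of the reference maximum (global), of the
#' local reference dose (local; zero-dose pixels are masked), or \code{dd}
#' Gy (absolute). Distances are physical (mm via pixel spacing); the
#' evaluation is a discrete minimum over measured pixel centers, with finer
#' agreement obtained by resampling the measured map first.
#'
#' If the two maps are not on the same grid the measured map is resampled
#' onto the reference geometry internally; reference pixels outside the
#' measured extent are excluded from evaluation.
#'
#' @param reference a [DoseMap-class]; the planned (TPS) map whose grid is
#'   evaluated
#' @param measured a [DoseMap-class]; the film measurement
#' @param criteria a [GammaCriteria-class]
#' @return a [GammaResult-class]
#' @export
gammaMatrix <- function(reference, measured, criteria = gammaCriteria()) {
  validObject(criteria)
  res <- measuredOnReferenceGrid(reference, measured)
  ref <- reference@dose
  mea <- res$dose
  sp <- reference@pixelSpacing
  dmax <- max(ref)
  stopIfNot(dmax > 0, "reference normalization dose must be positive")

  evaluated <- res$inside & (ref >= criteria@thresholdPercent / 100 * dmax)
  denom <- switch(criteria@normalization,
    global = criteria@ddPercent / 100 * dmax,
    local = criteria@ddPercent / 100 * ref,
    absolute = criteria@ddPercent)
  if (criteria@normalization == "local") {
    evaluated <- evaluated & (ref > 0)
    denom[denom <= 0] <- NA_real_
  }

  radius <- criteria@searchRadiusFactor * criteria@dtaMm
  d <- dim(ref)
  maxDr <- min(floor(radius / sp[1]), d[1] - 1L)
  maxDc <- min(floor(radius / sp[2]), d[2] - 1L)
  g2 <- matrix(Inf, d[1], d[2])
  dta2 <- criteria@dtaMm^2
  for (dr in -maxDr:maxDr) {
    for (dc in -maxDc:maxDc) {
      dist2 <- (dr * sp[1])^2 + (dc * sp[2])^2
      if (dist2 > radius^2 + 1e-12) next
      # shifted measured dose: candidate r_m = r_c + (dr, dc)
      rSrc <- seq_len(d[1]) + dr
      cSrc <- seq_len(d[2]) + dc
      okR <- rSrc >= 1L & rSrc <= d[1]
      okC <- cSrc >= 1L & cSrc <= d[2]
      if (!any(okR) || !any(okC)) next
      cand <- (ref[okR, okC, drop = FALSE] -
                 mea[rSrc[okR], cSrc[okC], drop = FALSE])^2 /
        (if (is.matrix(denom)) denom[okR, okC, drop = FALSE]^2 else denom^2) +
        dist2 / dta2
      g2[okR, okC] <- pmin(g2[okR, okC], cand)
    }
  }
  gamma <- sqrt(g2)
  gamma[!evaluated] <- NA_real_
  nEval <- sum(evaluated)
  pr <- if (nEval > 0) sum(gamma[evaluated] <= 1) / nEval else NA_real_
  new("GammaResult", gamma = gamma, evaluated = evaluated,
      passRate = pr, criteria = criteria)
}

#' Histogram of gamma values
#'
#' @param result a [GammaResult-class]
#' @param nBins number of equal-width bins from 0 to the maximum gamma
#' @return list with \code{binEdges} (length \code{nBins + 1}) and
#'   \code{counts} (length \code{nBins}, summing to the evaluated-pixel
#'   count)
#' @export
gammaHistogram <- function(result, nBins = 50L) {
  stopIfNot(nBins >= 1L, "nBins must be >= 1")
  g <- result@gamma[result@evaluated]
  stopIfNot(length(g) >= 1L, "no evaluated pixels")
  hi <- max(g, 1e-12)
  edges <- seq(0, hi, length.out = nBins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(g, edges, rightmost.closed = TRUE),
                               1L), nBins), nbins = nBins)
  list(binEdges = edges, counts = counts)
}
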