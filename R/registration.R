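# Film-to-plan registration: scanner-orientation pre-processing, normalized
# cross-correlation over all valid placements, small-angle rotation sweep,
# and crop of the matched region.

#' Scanner-orientation pre-processing
#'
#' Applies the transforms that bring a digitized film into the planning
#' coordinate frame: a vertical reflection followed by a 180-degree
#' rotation, in that order. Both default on (matching a scanner whose bed
#' mirrors the plan frame) and are individually togglable for other setups.
#'
#' @param filmDose numeric matrix (a reconstructed film dose grid)
#' @param flipVertical reverse the row order first
#' @param rotate180 then rotate by 180 degrees (reverse rows and columns)
#' @return transformed matrix
#' @export
preprocessFilm <- function(filmDose, flipVertical = TRUE, rotate180 = TRUE) {
  stopIfNot(length(filmDose) > 0, "empty grid")
  m <- filmDose
  if (flipVertical) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (rotate180) m <- m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
  m
}

# Cross-correlation of image with a (mean-subtracted) kernel over all valid
# placements, via circular FFT correlation with zero padding. Exact up to
# FFT round-off (~1e-12 relative).
crossCorrValid <- function(image, kernel) {
  n1 <- nrow(image); m1 <- ncol(image)
  n2 <- nrow(kernel); m2 <- ncol(kernel)
  kp <- matrix(0, n1, m1)
  kp[1:n2, 1:m2] <- kernel
  cc <- Re(stats::fft(stats::fft(image) * Conj(stats::fft(kp)),
                      inverse = TRUE)) / (n1 * m1)
  cc[1:(n1 - n2 + 1L), 1:(m1 - m2 + 1L), drop = FALSE]
}

# Window sums of image (and image^2) over template-sized windows at all
# valid placements, via exact integral images.
windowSums <- function(image, n2, m2) {
  s <- rbind(0, cbind(0, t(apply(apply(image, 2L, cumsum), 1L, cumsum))))
  n1 <- nrow(image); m1 <- ncol(image)
  r <- 1:(n1 - n2 + 1L); cl <- 1:(m1 - m2 + 1L)
  s[r + n2, cl + m2, drop = FALSE] - s[r, cl + m2, drop = FALSE] -
    s[r + n2, cl, drop = FALSE] + s[r, cl, drop = FALSE]
}

#' Normalized cross-correlation map
#'
#' For every placement of the template fully inside the image, computes
#' \deqn{E_{NCC} = \frac{\sum_i (I_0(x_i) - \bar I_0)(I_1(x_i+u) - \bar I_1)}
#'   {\sqrt{\sum_i (I_0(x_i) - \bar I_0)^2}\sqrt{\sum_i (I_1(x_i+u) - \bar I_1)^2}},}
#' where \eqn{I_0} is the template with its global mean \eqn{\bar I_0} and
#' \eqn{\bar I_1} is the local mean of the image window under the current
#' placement. Scores lie in \eqn{[-1, 1]} and are invariant to affine
#' intensity transforms of either input. Windows with zero variance
#' (uniform background) score 0 rather than erroring: they are legitimate
#' candidate positions that simply carry no correlation evidence.
#'
#' @param template numeric matrix, dims at most those of \code{image},
#'   non-zero variance
#' @param image numeric matrix
#' @return numeric matrix of size \code{(nrow(image)-nrow(template)+1) x
#'   (ncol(image)-ncol(template)+1)}
#' @export
nccMap <- function(template, image) {
  n2 <- nrow(template); m2 <- ncol(template)
  stopIfNot(n2 <= nrow(image) && m2 <= ncol(image),
            "template must not exceed the image")
  t0 <- template - mean(template)
  st <- sqrt(sum(t0^2))
  stopIfNot(st > 0, "zero-variance template")
  num <- crossCorrValid(image, t0)
  n <- n2 * m2
  s1 <- windowSums(image, n2, m2)
  s2 <- windowSums(image^2, n2, m2)
  var <- pmax(s2 - s1^2 / n, 0)
  den <- st * sqrt(var)
  out <- ifelse(den > 0, num / den, 0)
  pmin(pmax(out, -1), 1)
}

#' Locate the planned dose map inside the film
#'
#' Template-matching registration: the plan (template) is resampled to the
#' film's pixel spacing, rotated about its center by each angle in the sweep
#' (bilinear, out-of-bounds filled with the template's edge mean), and the
#' normalized cross-correlation over all valid placements is computed. The
#' global maximum over (angle, position) wins; ties break toward smaller
#' \code{abs(angle)}, then smaller row, then smaller column. Matching runs
#' on dose-converted images so the two intensities are commensurate.
#'
#' @param plan a [DoseMap-class], the planned (TPS) dose template
#' @param filmDose a [DoseMap-class], the reconstructed film dose
#' @param anglesDeg rotation sweep in degrees; the default covers the
#'   small-angle misalignments of a film placed by hand on a scanner bed
#' @return a [RegistrationResult-class]
#' @export
matchTemplate <- function(plan, filmDose,
                          anglesDeg = c(0, 1, -1, 2, -2, 3, -3)) {
  tmpl0 <- resampleToGrid(plan, filmDose@pixelSpacing)@dose
  img <- filmDose@dose
  if (nrow(tmpl0) > nrow(img) || ncol(tmpl0) > ncol(img))
    stop("plan is larger than the film after resampling", call. = FALSE)
  ord <- order(abs(anglesDeg), -sign(anglesDeg))
  best <- NULL
  for (a in anglesDeg[ord]) {
    tmpl <- rotateBilinear(tmpl0, a)
    sc <- nccMap(tmpl, img)
    mx <- max(sc)
    if (is.null(best) || mx > best$score + 1e-12) {
      hit <- which(sc == mx, arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
      best <- list(score = mx, angle = a, offset = hit, map = sc)
    }
  }
  new("RegistrationResult",
      offsetPx = as.integer(best$offset),
      angleDeg = best$angle,
      nccScore = best$score,
      scoreMap = best$map,
      anglesTried = anglesDeg[ord])
}

#' Crop the matched film region
#'
#' Extracts the film sub-grid located by [matchTemplate()] with the plan's
#' shape, then inverse-rotates it by the matched angle so the crop lies in
#' the plan's frame. Spacing is the film's; the crop origin is reset to
#' (0, 0) of the plan frame.
#'
#' @param filmDose a [DoseMap-class]
#' @param result a [RegistrationResult-class] for this film
#' @param planShape integer length-2 (rows, cols) of the template in film
#'   pixels
#' @return a [DoseMap-class] in the plan's frame
#' @export
cropMatched <- function(filmDose, result, planShape) {
  off <- result@offsetPx
  r <- off[1]:(off[1] + planShape[1] - 1L)
  cl <- off[2]:(off[2] + planShape[2] - 1L)
  d <- dim(filmDose@dose)
  if (max(r) > d[1] || max(cl) > d[2])
    stop("crop exceeds the film bounds", call. = FALSE)
  sub <- filmDose@dose[r, cl, drop = FALSE]
  if (result@angleDeg != 0)
    sub <- pmax(rotateBilinear(sub, -result@angleDeg), 0)
  DoseMap(sub, pixelSpacing = filmDose@pixelSpacing, origin = c(0, 0))
}
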