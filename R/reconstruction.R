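# Dose reconstruction from scanned films: per-pixel single-channel lookup
# and the multichannel disturbance-separation method.

CHANNEL_INDEX <- c(R = 1L, G = 2L, B = 3L)

# Per-channel post/pre optical densities of a film. preScan may be NULL
# (unirradiated reference: T_i = 1, OD_i = 0), a scalar or length-3 PV
# reference, or a ScannedFilm of identical shape.
filmOpticalDensities <- function(film, preScan = NULL) {
  pvmax <- 2^film@bitDepth - 1
  tmin <- 1 / pvmax
  d <- dim(film@pixels)
  odf <- array(0, d)
  for (k in 1:3)
    odf[, , k] <- -log10(pmax(film@pixels[, , k] / pvmax, tmin))
  odi <- array(0, d)
  if (is(preScan, "ScannedFilm")) {
    stopIfNot(identical(dim(preScan@pixels), d),
              "pre-scan dimensions must match the film")
    for (k in 1:3)
      odi[, , k] <- -log10(pmax(preScan@pixels[, , k] / pvmax, tmin))
  } else if (is.numeric(preScan)) {
    ref <- if (length(preScan) == 1L) rep(preScan, 3L) else preScan
    stopIfNot(length(ref) == 3L, "numeric pre-scan reference must be length 1 or 3")
    for (k in 1:3)
      odi[, , k] <- -log10(max(ref[k] / pvmax, tmin))
  } else if (!is.null(preScan)) {
    stop("preScan must be NULL, a numeric PV reference, or a ScannedFilm",
         call. = FALSE)
  }
  list(odf = odf, odi = odi)
}

# Net response per channel at scaling factor t (t = 1: raw measurement).
# The multichannel scaling acts on optical density, as the disturbance
# model is multiplicative in OD: both the post and pre OD are scaled, then
# the response the calibration expects is recomputed.
scaledResponse <- function(odf, odi, t, responseKind) {
  if (responseKind == "net_od") {
    (odf - odi) * t
  } else {
    10^(-odf * t) - 10^(-odi * t)
  }
}

#' Single-channel dose reconstruction
#'
#' Applies one channel's calibration function point by point to the
#' digitized film: per pixel, the net response of the requested channel is
#' computed (against a pre-scan, a scalar unirradiated PV reference, or the
#' full-scale default) and converted to dose. Negative model outputs are
#' clamped to zero and counted in the result's metadata.
#'
#' @param film a [ScannedFilm-class]
#' @param model a [CalibrationModel-class] for the requested channel
#' @param channel \code{"R"}, \code{"G"} or \code{"B"}; must match the model
#' @param preScan optional [ScannedFilm-class] or numeric PV reference
#' @return a [DoseMap-class]; \code{attr(, "nClamped")} counts negative
#'   doses clamped to zero
#' @export
singleChannelDose <- function(film, model, channel = model@channel,
                              preScan = NULL) {
  if (!identical(model@channel, channel))
    stop(sprintf("channel mismatch: model is for %s, requested %s",
                 model@channel, channel), call. = FALSE)
  k <- CHANNEL_INDEX[[channel]]
  od <- filmOpticalDensities(film, preScan)
  resp <- scaledResponse(od$odf[, , k], od$odi[, , k], 1, model@responseKind)
  dose <- evalModel(model@modelKind, model@params, resp)
  nClamped <- sum(dose < 0)
  dose <- pmax(dose, 0)
  out <- DoseMap(dose, pixelSpacing = film@pixelSpacing)
  attr(out, "nClamped") <- nClamped
  out
}

# Pairwise-disagreement objective of the multichannel method, vectorised
# over pixels: g(t) = sum_{i<j} (D_i(t) - D_j(t))^2. odf/odi are n x 3
# matrices of optical densities; t is length n.
channelDoses <- function(odf, odi, t, models) {
  D <- matrix(0, length(t), 3L)
  for (k in 1:3) {
    m <- models[[k]]
    r <- scaledResponse(odf[, k], odi[, k], t, m@responseKind)
    D[, k] <- evalModel(m@modelKind, m@params, r)
  }
  D
}

pairObjective <- function(odf, odi, t, models) {
  D <- channelDoses(odf, odi, t, models)
  (D[, 1] - D[, 2])^2 + (D[, 1] - D[, 3])^2 + (D[, 2] - D[, 3])^2
}

# Golden-section search on [lo, hi] for pixels where Newton failed.
goldenSection <- function(fn, lo = 0.5, hi = 1.5, tol = 1e-7, maxIter = 200L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- fn(c1); f2 <- fn(c2)
  for (i in seq_len(maxIter)) {
    if (b - a < tol) break
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- fn(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- fn(c2)
    }
  }
  (a + b) / 2
}

#' Multichannel dose reconstruction
#'
#' The multichannel method separates the dose-dependent film response from
#' dose-independent disturbances (film or scanner non-homogeneities). For
#' each pixel it finds the scaling factor t minimizing the pairwise channel
#' disagreement
#' \deqn{g(t) = \sum_{i<j} \left(D_i(t) - D_j(t)\right)^2,}
#' where \eqn{D_i(t)} is the dose predicted by channel i's calibration with
#' its optical density scaled by t (the unordered-pair sum is half the full
#' ordered sum and has the same argmin). Newton-Raphson iterates on
#' \eqn{g'(t) = 0} from \eqn{t_0 = 1} with at most \code{maxIter}
#' iterations and tolerance \eqn{|\Delta t| < 10^{-6}}; derivatives are
#' 5-point central finite differences of g. Pixels where Newton diverges
#' fall back to a golden-section search on \eqn{t \in [0.5, 1.5]}; if that
#' only finds a boundary minimum the pixel is flagged non-converged and
#' filled with the red-channel single-channel dose (reported, never a hole).
#' The final dose is the arithmetic mean of the three channel doses at
#' \eqn{t_{\min}}; the t-map itself images the separated non-homogeneities.
#'
#' @param film a [ScannedFilm-class]
#' @param models list of three [CalibrationModel-class] for channels R, G, B
#'   (named or in that order), all with the same response kind
#' @param preScan optional [ScannedFilm-class] or numeric PV reference
#' @param maxIter maximum Newton iterations per pixel
#' @param tol convergence tolerance on \eqn{|\Delta t|}
#' @return a [MultichannelResult-class]
#' @export
multichannelDose <- function(film, models, preScan = NULL, maxIter = 100L,
                             tol = 1e-6) {
  stopIfNot(length(models) == 3L, "need one calibration model per channel")
  if (!is.null(names(models)) && all(c("R", "G", "B") %in% names(models)))
    models <- models[c("R", "G", "B")]
  kinds <- vapply(models, function(m) m@responseKind, character(1))
  stopIfNot(length(unique(kinds)) == 1L,
            "all channel models must share one response kind")
  d <- dim(film@pixels)
  od <- filmOpticalDensities(film, preScan)
  n <- d[1] * d[2]
  odf <- matrix(od$odf, n, 3L)
  odi <- matrix(od$odi, n, 3L)

  g <- function(t, idx) pairObjective(odf[idx, , drop = FALSE],
                                      odi[idx, , drop = FALSE], t, models)
  t <- rep(1, n)
  iters <- integer(n)
  # pixels whose channels already agree at t = 1 (e.g. unexposed background,
  # consistent noise-free films) are converged by construction
  active <- g(rep(1, n), seq_len(n)) >= 1e-18
  bad <- rep(FALSE, n)
  h <- 1e-5
  for (it in seq_len(maxIter)) {
    idx <- which(active)
    if (!length(idx)) break
    tc <- t[idx]
    gm <- g(tc - h, idx); g0 <- g(tc, idx); gp <- g(tc + h, idx)
    g1 <- (gp - gm) / (2 * h)
    g2 <- (gp - 2 * g0 + gm) / h^2
    step <- ifelse(g2 > 0, g1 / g2, NA_real_)
    tn <- tc - step
    # the objective has a degenerate root at t = 0 (all channel doses
    # vanish), so the search is trusted only on [0.5, 1.5] around the
    # physical no-disturbance value t = 1
    diverged <- !is.finite(tn) | tn < 0.5 | tn > 1.5
    done <- !diverged & abs(step) < tol
    t[idx] <- ifelse(diverged, tc, tn)
    iters[idx] <- it
    bad[idx[diverged]] <- TRUE
    active[idx[diverged | done]] <- FALSE
  }
  bad[active] <- TRUE  # ran out of iterations

  # fallback: bounded golden-section search per flagged pixel
  conv <- !bad
  for (i in which(bad)) {
    fn <- function(tt) g(tt, i)
    tm <- goldenSection(fn, 0.5, 1.5, tol = tol)
    if (tm > 0.5 + 10 * tol && tm < 1.5 - 10 * tol) {
      t[i] <- tm
      conv[i] <- TRUE
    }
  }
  t[!conv] <- 1  # neutral scaling for flagged pixels
  # never worsen channel agreement relative to the unscaled measurement
  worse <- g(t, seq_len(n)) > g(rep(1, n), seq_len(n))
  t[worse] <- 1

  D <- channelDoses(odf, odi, t, models)
  dose <- rowMeans(D)
  redDose <- evalModel(models[[1]]@modelKind, models[[1]]@params,
                       scaledResponse(odf[, 1], odi[, 1], 1,
                                      models[[1]]@responseKind))
  dose[!conv] <- redDose[!conv]
  dose <- pmax(dose, 0)
  new("MultichannelResult",
      dose = DoseMap(matrix(dose, d[1], d[2]),
                     pixelSpacing = film@pixelSpacing),
      tMap = matrix(t, d[1], d[2]),
      iterations = matrix(iters, d[1], d[2]),
      converged = matrix(conv, d[1], d[2]))
}
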