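# Dose-response calibration: rational (net transmittance) and polynomial
# (net optical density) model families, weighted Levenberg-Marquardt fits,
# closed-form / bisection inversion, and JSON (de)serialization.

#' Rational dose-response function
#'
#' \deqn{D = \frac{A\, netT}{1 - B\, netT}} — the manufacturer-style rational
#' calibration on net transmittance. With \eqn{A < 0, B > 0} it is monotone
#' decreasing on \eqn{netT \in (-1, 0]} (a darkening film gives negative
#' netT and positive dose).
#'
#' @param params numeric length-2 \code{c(A, B)}
#' @param netT net transmittance value(s)
#' @return dose in Gy
#' @examples
#' rationalDose(c(-20, 2), -0.2)  # 4/1.4 = 2.857143 Gy
#' @export
rationalDose <- function(params, netT) {
  A <- unname(params[1]); B <- unname(params[2])
  den <- 1 - B * netT
  if (any(abs(den) < 1e-12))
    stop("rational model pole: 1 - B*netT vanishes", call. = FALSE)
  A * netT / den
}

#' Polynomial dose-response function
#'
#' \deqn{D = A\, netOD + B\, netOD^{\,n}} on net optical density.
#'
#' @param params numeric length-3 \code{c(A, B, n)}
#' @param netOD net optical density value(s)
#' @return dose in Gy
#' @examples
#' polynomialDose(c(10, 50, 2), 0.1)  # 1.5 Gy
#' @export
polynomialDose <- function(params, netOD) {
  A <- unname(params[1]); B <- unname(params[2]); n <- unname(params[3])
  if (any(netOD < 0) && abs(n - round(n)) > 1e-9)
    stop("negative netOD with fractional exponent n is undefined", call. = FALSE)
  A * netOD + B * sign(netOD) * abs(netOD)^n
}

# Model evaluation without range checks; sign-safe power continuation used
# during fitting so noisy zero-dose points cannot abort the optimizer.
evalModel <- function(kind, params, response) {
  params <- unname(params)
  if (kind == "rational") {
    den <- 1 - params[2] * response
    den[abs(den) < 1e-12] <- 1e-12
    params[1] * response / den
  } else {
    params[1] * response +
      params[2] * sign(response) * abs(response)^params[3]
  }
}

rationalInit <- function(response, dose) {
  pos <- which(dose > 0)
  i <- pos[which.min(dose[pos])]; j <- pos[which.max(dose[pos])]
  M <- rbind(c(response[i], response[i] * dose[i]),
             c(response[j], response[j] * dose[j]))
  b <- c(dose[i], dose[j])
  p <- tryCatch(solve(M, b), error = function(e) NULL)
  if (is.null(p) || any(!is.finite(p))) {
    A0 <- dose[j] / response[j]
    p <- c(A0, 0)
  }
  p
}

polynomialInit <- function(response, dose) {
  pos <- which(dose > 0 & response != 0)
  i <- pos[which.min(dose[pos])]; j <- pos[which.max(dose[pos])]
  A0 <- dose[i] / response[i]
  resid <- dose[j] - A0 * response[j]
  n0 <- 2
  B0 <- if (resid > 0) resid / abs(response[j])^n0 else 1
  c(A0, B0, n0)
}

#' Fit a calibration model
#'
#' Weighted least-squares fit of dose as a function of net response via
#' Levenberg-Marquardt, minimizing \eqn{\sum_i w_i (D_i - f(r_i))^2} with
#' inverse-variance weights \eqn{w_i = 1/\sigma_i^2} when response
#' uncertainties are supplied (all positive), unweighted otherwise; equal
#' sigmas therefore reproduce the unweighted fit exactly. Approximate
#' parameter uncertainties come from the Jacobian at the optimum. The fit
#' refuses to return if the optimizer did not converge.
#'
#' @param kind \code{"rational"} (params A, B on netT) or
#'   \code{"polynomial"} (params A, B, n on netOD)
#' @param response net responses (netT or netOD per \code{kind})
#' @param dose absorbed doses in Gy, distinct values
#' @param sigma optional response uncertainties (same length); all positive
#'   for a weighted fit, NULL/all-zero for unweighted
#' @param channel \code{"R"}, \code{"G"} or \code{"B"}
#' @param fixedN optional fixed polynomial exponent (fits A, B only)
#' @param doseRange calibrated dose range in Gy
#' @return a [CalibrationModel-class]
#' @export
fitCalibration <- function(kind = c("rational", "polynomial"), response, dose,
                           sigma = NULL, channel = "R", fixedN = NULL,
                           doseRange = c(0, 10)) {
  kind <- match.arg(kind)
  nFree <- if (kind == "rational" || !is.null(fixedN)) 2L else 3L
  stopIfNot(length(response) == length(dose), "response/dose lengths differ")
  stopIfNot(length(dose) >= nFree + 1L,
            sprintf("need at least %d points for a %d-parameter fit",
                    nFree + 1L, nFree))
  stopIfNot(!anyDuplicated(dose), "doses must be distinct")
  weighted <- !is.null(sigma) && all(sigma > 0)
  if (!is.null(sigma) && !weighted && any(sigma > 0))
    warning("some sigmas are zero: falling back to unweighted fit")

  p0 <- if (kind == "rational") rationalInit(response, dose)
        else polynomialInit(response, dose)
  if (!is.null(fixedN) && kind == "polynomial") p0 <- p0[1:2]

  fullPar <- function(p) {
    if (kind == "polynomial" && !is.null(fixedN)) c(p, fixedN) else p
  }
  w <- if (weighted) 1 / sigma^2 else rep(1, length(dose))
  sw <- sqrt(w / mean(w))  # normalised so the residual scale stays in Gy
  residFun <- function(p) sw * (dose - evalModel(kind, fullPar(p), response))

  fit <- minpack.lm::nls.lm(par = p0, fn = residFun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, maxfev = 5000,
                              ftol = 1e-15, ptol = 1e-15))
  if (!fit$info %in% 1:4)
    stop(sprintf("calibration fit did not converge: %s", fit$message),
         call. = FALSE)
  p <- fit$par
  nObs <- length(dose)
  dof <- nObs - length(p)
  redChi <- fit$deviance / max(dof, 1L)
  # parameter covariance from the Jacobian at the optimum, scaled by the
  # residual variance (singular Jacobian -> explicit error)
  hinv <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (is.null(hinv))
    stop("singular Jacobian at the fit optimum", call. = FALSE)
  psig <- sqrt(pmax(diag(hinv), 0) * redChi)
  pred <- evalModel(kind, fullPar(p), response)
  rsq <- 1 - sum((dose - pred)^2) / sum((dose - mean(dose))^2)
  params <- fullPar(p)
  names(params) <- if (kind == "rational") c("A", "B") else c("A", "B", "n")
  paramSigma <- setNames(rep(0, length(params)), names(params))
  paramSigma[seq_along(psig)] <- psig
  new("CalibrationModel", modelKind = kind, channel = channel,
      params = params, paramSigma = paramSigma,
      responseKind = if (kind == "rational") "net_t" else "net_od",
      doseRange = as.numeric(doseRange),
      gof = list(redChiSq = redChi, rSquared = rsq, nPoints = nObs,
                 converged = TRUE))
}

#' Evaluate a calibration model
#'
#' @param model a [CalibrationModel-class]
#' @param response net response value(s) (netT or netOD per the model's
#'   response kind)
#' @return dose in Gy
#' @export
predictDose <- function(model, response) {
  if (model@modelKind == "rational") rationalDose(model@params, response)
  else polynomialDose(model@params, response)
}

# Response value at the upper end of the calibrated dose range, on the
# monotone branch through response = 0 (D = 0). Rational models invert in
# closed form; polynomial models bracket by doubling.
responseAtDose <- function(model, dose) {
  p <- model@params
  if (model@modelKind == "rational") {
    den <- p["A"] + p["B"] * dose
    if (any(abs(den) < 1e-12))
      stop("rational inverse pole: A + B*D vanishes", call. = FALSE)
    unname(dose / den)
  } else {
    vapply(dose, function(d) {
      if (d == 0) return(0)
      hi <- 0.1
      while (evalModel("polynomial", p, hi) < d && hi < 1e3) hi <- hi * 2
      if (evalModel("polynomial", p, hi) < d)
        stop(sprintf(paste0("model cannot reach %g Gy on its monotone ",
                            "branch"), d), call. = FALSE)
      uniroot(function(r) evalModel("polynomial", p, r) - d,
              c(0, hi), tol = 1e-13)$root
    }, numeric(1))
  }
}

#' Invert a calibration model: dose to response
#'
#' Finds the net response r with \eqn{f(r) = D} on the model's monotone
#' branch, for doses inside the calibrated range. Rational models use the
#' closed form \eqn{r = D/(A + B D)}; polynomial models solve by bisection
#' to \eqn{|\Delta D| < 10^{-9}} Gy. Models that are not monotone over the
#' calibrated range are refused.
#'
#' @param model a [CalibrationModel-class]
#' @param dose dose value(s) in Gy within the model's dose range
#' @return net response value(s)
#' @export
invertDose <- function(model, dose) {
  rng <- model@doseRange
  if (any(dose < rng[1] - 1e-9 | dose > rng[2] + 1e-9))
    stop(sprintf("dose outside calibrated range [%g, %g] Gy", rng[1], rng[2]),
         call. = FALSE)
  assertMonotone(model)
  responseAtDose(model, dose)
}

assertMonotone <- function(model) {
  rng <- model@doseRange
  rEnd <- tryCatch(responseAtDose(model, rng[2]), error = function(e)
    stop("model is not monotone over the calibrated range: ",
         conditionMessage(e), call. = FALSE))
  rr <- seq(0, rEnd, length.out = 256)
  dd <- evalModel(model@modelKind, model@params, rr)
  dv <- diff(dd)
  if (any(dv > 1e-12) && any(dv < -1e-12))
    stop("model is not monotone over the calibrated range", call. = FALSE)
  invisible(TRUE)
}

#' Serialize calibration models to JSON
#'
#' @param models a [CalibrationModel-class] or list of them
#' @param path output JSON path
#' @return invisibly, the path
#' @export
writeCalibration <- function(models, path) {
  if (is(models, "CalibrationModel")) models <- list(models)
  doc <- lapply(models, function(m) list(
    model_kind = m@modelKind, channel = m@channel,
    params = as.list(m@params), param_sigma = as.list(m@paramSigma),
    response_kind = m@responseKind, dose_range_gy = m@doseRange,
    gof = m@gof))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read calibration models from JSON
#'
#' @param path JSON path written by [writeCalibration()]
#' @return list of [CalibrationModel-class], named by channel
#' @export
readCalibration <- function(path) {
  stopIfNot(file.exists(path), sprintf("calibration file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(doc, function(d) {
    new("CalibrationModel", modelKind = d$model_kind, channel = d$channel,
        params = unlist(d$params), paramSigma = unlist(d$param_sigma),
        responseKind = d$response_kind,
        doseRange = as.numeric(unlist(d$dose_range_gy)),
        gof = lapply(d$gof, function(x) if (is.list(x)) unlist(x) else x))
  })
  names(models) <- vapply(models, function(m) m@channel, character(1))
  models
}
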