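# End-to-end QA orchestration: calibrate -> reconstruct -> register -> crop
# -> gamma, behind a validated configuration document. Every stage logs its
# parameters; reports are machine-readable JSON and bit-identical across
# re-runs with the same configuration and seeds.

#' Read and validate a run configuration
#'
#' Loads a YAML or JSON configuration document (by file extension) and
#' checks that every referenced input file exists. See [runCalibrate()] and
#' [runCompare()] for the sections each stage uses.
#'
#' @param path configuration file (.yaml/.yml or .json)
#' @return validated configuration list
#' @export
readRunConfig <- function(path) {
  stopIfNot(file.exists(path), sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- character(0)
  cal <- cfg$calibration
  if (!is.null(cal))
    for (lev in cal$doses)
      missing <- c(missing, Filter(Negate(file.exists), unlist(lev$films)))
  for (p in c(cfg$paths$film, cfg$paths$plan, cfg$paths$pre_scan,
              cfg$reconstruction$models))
    if (!is.null(p) && !file.exists(p)) missing <- c(missing, p)
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cfg
}

logStage <- function(stage, ..., quiet = FALSE) {
  if (!quiet)
    message(sprintf("[%s] %s", stage, paste(sprintf(...), collapse = "")))
}

idealPreStats <- function(bitDepth) {
  pvmax <- 2^bitDepth - 1
  list(meanPv = setNames(rep(pvmax, 3), c("R", "G", "B")),
       sdPv = setNames(rep(0, 3), c("R", "G", "B")), nPixels = 1L)
}

#' Run the calibration stage
#'
#' For every dose level in the configuration's calibration table, extracts
#' ROI statistics from each replicate film, forms net responses against the
#' pre-scan (or the full-scale unirradiated reference), combines replicates
#' by the inverse-variance weighted average, and fits the requested model
#' per channel. Fitted models and a fit report are written to the output
#' directory as JSON.
#'
#' Configuration section \code{calibration}: \code{model}
#' (rational/polynomial), \code{channels}, \code{dose_range}, \code{dpi},
#' \code{roi} (row0, col0, height, width), optional \code{pre_scan} path,
#' and \code{doses}, a list of \code{dose_gy} + \code{films} (replicate
#' TIFF paths).
#'
#' @param config configuration list (see [readRunConfig()])
#' @param quiet suppress stage logging
#' @return invisibly, a list with \code{models} (per channel),
#'   \code{modelsPath}, \code{reportPath}
#' @export
runCalibrate <- function(config, quiet = FALSE) {
  cal <- config$calibration
  stopIfNot(!is.null(cal), "configuration lacks a calibration section")
  stopIfNot(length(cal$doses) >= 4L, "need at least 4 dose levels")
  outDir <- config$output_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  kind <- cal$model %||% "rational"
  channels <- cal$channels %||% c("R", "G", "B")
  doseRange <- as.numeric(cal$dose_range %||% c(0, 10))
  dpi <- cal$dpi
  roi <- as.integer(cal$roi)
  bitDepth <- 16L

  missing <- unlist(lapply(cal$doses, function(lev)
    Filter(Negate(file.exists), unlist(lev$films))))
  if (length(missing))
    stop("missing calibration film(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  preStats <- if (!is.null(cal$pre_scan)) {
    pre <- readTiffFilm(cal$pre_scan, dpi = dpi)
    bitDepth <- pre@bitDepth
    roiStatistics(pre, roi)
  } else NULL

  respCol <- if (kind == "rational") "netT" else "netOD"
  sigCol <- if (kind == "rational") "sigmaNetT" else "sigmaNetOD"

  doses <- vapply(cal$doses, function(l) as.numeric(l$dose_gy), numeric(1))
  logStage("calibrate", "model=%s, %d dose levels, roi=(%s)", kind,
           length(doses), paste(roi, collapse = ","), quiet = quiet)

  agg <- lapply(cal$doses, function(lev) {
    reps <- lapply(unlist(lev$films), function(p) {
      film <- readTiffFilm(p, dpi = dpi)
      pre <- preStats %||% idealPreStats(film@bitDepth)
      netResponse(pre, roiStatistics(film, roi), film@bitDepth)
    })
    sapply(c("R", "G", "B"), function(ch) {
      vals <- vapply(reps, function(r) r[r$channel == ch, respCol], numeric(1))
      sig <- vapply(reps, function(r) r[r$channel == ch, sigCol], numeric(1))
      if (any(sig == 0) && any(sig > 0)) sig <- rep(0, length(sig))
      weightedNetOD(vals, sig)
    })
  })

  models <- lapply(channels, function(ch) {
    resp <- vapply(agg, function(a) a["mean", ch], numeric(1))
    sig <- vapply(agg, function(a) a["sigma", ch], numeric(1))
    fitCalibration(kind, resp, doses,
                   sigma = if (all(sig > 0)) sig else NULL,
                   channel = ch, doseRange = doseRange)
  })
  names(models) <- channels

  modelsPath <- file.path(outDir, "calibration_models.json")
  writeCalibration(models, modelsPath)
  report <- lapply(models, function(m) list(
    channel = m@channel, model_kind = m@modelKind, params = as.list(m@params),
    param_sigma = as.list(m@paramSigma), gof = m@gof))
  reportPath <- file.path(outDir, "calibration_report.json")
  jsonlite::write_json(list(model = kind, dose_levels = doses,
                            dose_range_gy = doseRange, fits = report),
                       reportPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  for (m in models)
    logStage("calibrate", "channel %s: %s, R^2=%.6f", m@channel,
             paste(sprintf("%s=%.5g", names(m@params), m@params),
                   collapse = " "), m@gof$rSquared, quiet = quiet)
  invisible(list(models = models, modelsPath = modelsPath,
                 reportPath = reportPath))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the plan-to-film comparison stage
#'
#' Full verification pipeline: reconstruct the film dose map (single or
#' multichannel), denoise it, apply the scanner-orientation pre-processing,
#' register the planned map inside the film by normalized cross-correlation
#' (or a manual offset/angle override), crop the matched region, resample to
#' the plan grid, and run the gamma test. Writes the gamma map (DICOM RT
#' Dose dialect) plus a JSON report recording the full criteria, the
#' registration, histogram data, and the pass rate.
#'
#' Configuration sections: \code{paths} (\code{film}, \code{plan}, optional
#' \code{pre_scan}), \code{reconstruction} (\code{method} single or
#' multichannel, \code{channel}, \code{models} JSON path or in-memory
#' \code{config$models}, \code{median_size}, \code{wiener_window},
#' \code{dpi}), \code{registration} (\code{angles}, \code{flip_vertical},
#' \code{rotate_180}, \code{manual_offset}, \code{manual_angle},
#' \code{min_score}), \code{gamma} (\code{dd}, \code{dta},
#' \code{threshold}, \code{normalization}).
#'
#' @param config configuration list (see [readRunConfig()])
#' @param quiet suppress stage logging
#' @return invisibly, a list with \code{gamma} ([GammaResult-class]),
#'   \code{registration}, \code{filmDose}, \code{measured} (crop on the
#'   plan grid), \code{reportPath}
#' @export
runCompare <- function(config, quiet = FALSE) {
  outDir <- config$output_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rec <- config$reconstruction %||% list()
  reg <- config$registration %||% list()
  gam <- config$gamma %||% list()

  models <- config$models %||% readCalibration(rec$models)
  film <- if (is(config$film, "ScannedFilm")) config$film
          else readTiffFilm(config$paths$film, dpi = rec$dpi)
  plan <- if (is(config$plan, "DoseMap")) config$plan
          else readRTDose(config$paths$plan)
  preScan <- if (!is.null(config$paths$pre_scan))
    readTiffFilm(config$paths$pre_scan, dpi = rec$dpi) else NULL

  method <- rec$method %||% "single"
  logStage("reconstruct", "method=%s", method, quiet = quiet)
  filmDose <- if (method == "multichannel") {
    mc <- multichannelDose(film, models, preScan = preScan)
    logStage("reconstruct", "%d non-converged pixel(s)",
             sum(!mc@converged), quiet = quiet)
    mc@dose
  } else {
    ch <- rec$channel %||% "R"
    singleChannelDose(film, models[[ch]], ch, preScan = preScan)
  }

  med <- rec$median_size %||% 3L
  wien <- rec$wiener_window %||% 1L
  logStage("denoise", "median=%d, wiener=%d", med, wien, quiet = quiet)
  den <- denoiseImage(filmDose@dose, med, wien)

  flipV <- reg$flip_vertical %||% TRUE
  rot180 <- reg$rotate_180 %||% TRUE
  logStage("preprocess", "flip_vertical=%s, rotate_180=%s", flipV, rot180,
           quiet = quiet)
  pre <- preprocessFilm(den, flipV, rot180)
  filmDoseMap <- DoseMap(pmax(pre, 0), pixelSpacing = filmDose@pixelSpacing)

  planShape <- dim(resampleToGrid(plan, filmDoseMap@pixelSpacing)@dose)
  if (!is.null(reg$manual_offset)) {
    result <- new("RegistrationResult",
                  offsetPx = as.integer(reg$manual_offset),
                  angleDeg = reg$manual_angle %||% 0,
                  nccScore = 1, scoreMap = matrix(1, 1, 1),
                  anglesTried = numeric(0))
    logStage("register", "manual override offset=(%d,%d), angle=%.2f",
             result@offsetPx[1], result@offsetPx[2], result@angleDeg,
             quiet = quiet)
  } else {
    angles <- as.numeric(reg$angles %||% c(0, 1, -1, 2, -2, 3, -3))
    result <- matchTemplate(plan, filmDoseMap, angles)
    logStage("register", "offset=(%d,%d), angle=%.2f, NCC=%.5f",
             result@offsetPx[1], result@offsetPx[2], result@angleDeg,
             result@nccScore, quiet = quiet)
    floorScore <- reg$min_score %||% 0.2
    if (result@nccScore < floorScore)
      stop(sprintf(paste0("registration NCC score %.3f below floor %.3f: ",
                          "check orientation flags or supply manual_offset/",
                          "manual_angle"), result@nccScore, floorScore),
           call. = FALSE)
  }

  crop <- cropMatched(filmDoseMap, result, planShape)
  measured <- resampleToGrid(crop, plan@pixelSpacing)
  measured@origin <- plan@origin
  # align grids exactly (resampling can differ by one edge pixel)
  dp <- dim(plan@dose); dmv <- dim(measured@dose)
  if (!identical(dp, dmv)) {
    common <- pmin(dp, dmv)
    measured@dose <- measured@dose[seq_len(common[1]), seq_len(common[2]),
                                   drop = FALSE]
    plan@dose <- plan@dose[seq_len(common[1]), seq_len(common[2]),
                           drop = FALSE]
  }

  crit <- gammaCriteria(gam$dd %||% 3, gam$dta %||% 3, gam$threshold %||% 5,
                        gam$normalization %||% "global",
                        gam$search_radius_factor %||% 3)
  gr <- gammaMatrix(plan, measured, crit)
  logStage("gamma", "%g%%/%g mm (%s), threshold %g%%: pass rate %.2f%%",
           crit@ddPercent, crit@dtaMm, crit@normalization,
           crit@thresholdPercent, 100 * gr@passRate, quiet = quiet)

  gammaPath <- file.path(outDir, "gamma_map.dcm")
  gclean <- gr@gamma
  gclean[is.na(gclean)] <- 0
  writeRTDose(DoseMap(gclean, pixelSpacing = plan@pixelSpacing,
                      origin = plan@origin), gammaPath)
  hist <- gammaHistogram(gr, 50L)
  reportPath <- file.path(outDir, "compare_report.json")
  jsonlite::write_json(list(
    criteria = list(dd_percent = crit@ddPercent, dta_mm = crit@dtaMm,
                    threshold_percent = crit@thresholdPercent,
                    normalization = crit@normalization,
                    search_radius_factor = crit@searchRadiusFactor),
    reconstruction = list(method = method,
                          median_size = med, wiener_window = wien),
    registration = list(offset_px = result@offsetPx,
                        angle_deg = result@angleDeg,
                        ncc_score = result@nccScore),
    pass_rate = gr@passRate,
    evaluated_pixels = sum(gr@evaluated),
    gamma_mean = mean(gr@gamma[gr@evaluated]),
    gamma_max = max(gr@gamma[gr@evaluated]),
    histogram = list(bin_edges = hist$binEdges, counts = hist$counts)),
    reportPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(gamma = gr, registration = result, filmDose = filmDoseMap,
                 measured = measured, reportPath = reportPath,
                 gammaPath = gammaPath))
}
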