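# End-to-end orchestration: calibration runs over film sets, comparison
# runs over film + plan, configuration validation.

writeCalibrationSet <- function(dir, doses, nReps = 3, noiseFrac = 0,
                                seed0 = 100, size = 14L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  levels <- lapply(seq_along(doses), function(i) {
    films <- vapply(seq_len(nReps), function(r) {
      dose <- DoseMap(matrix(doses[i], size, size), c(1, 1))
      film <- filmFromDose(dose, fixtureModels,
                           scannerNoiseSpec(gaussianSigmaFraction = noiseFrac,
                                            seed = seed0 + i * 10 + r))
      p <- file.path(dir, sprintf("cal_d%02d_r%d.tif", i, r))
      writeTiffFilm(film, p)
      p
    }, character(1))
    list(dose_gy = doses[i], films = as.list(films))
  })
  levels
}

test_that("calibration over synthetic film sets recovers the truth", {
  dir <- tempfile("calset")
  doses <- seq(0, 10, length.out = 9)
  cfg <- list(
    output_dir = file.path(dir, "out"),
    calibration = list(model = "rational", channels = c("R", "G", "B"),
                       dose_range = c(0, 10), dpi = 25.4,
                       roi = c(3, 3, 10, 10),
                       doses = writeCalibrationSet(dir, doses)))
  res <- runCalibrate(cfg, quiet = TRUE)
  # recovery limited only by 16-bit scanner quantization of the films
  for (ch in c("R", "G", "B")) {
    truth <- modelParams(fixtureModels[[ch]])
    got <- modelParams(res$models[[ch]])
    expect_lt(max(abs(got - truth) / abs(truth)), 5e-3)
    expect_gt(res$models[[ch]]@gof$rSquared, 1 - 1e-6)
  }
  expect_true(file.exists(res$modelsPath))
  expect_true(file.exists(res$reportPath))
  back <- readCalibration(res$modelsPath)
  expect_equal(modelParams(back$R), modelParams(res$models$R))
})

test_that("replicate aggregation matches the weighted-average formulas", {
  # two replicates with distinct scatter: the aggregated response must be
  # the inverse-variance weighted mean of the per-replicate responses
  dir <- tempfile("calrep")
  doses <- c(0, 2, 5, 8, 10)
  levels <- writeCalibrationSet(dir, doses, nReps = 2, noiseFrac = 0.01,
                                seed0 = 300)
  cfg <- list(output_dir = file.path(dir, "out"),
              calibration = list(model = "rational", channels = "R",
                                 dose_range = c(0, 10), dpi = 25.4,
                                 roi = c(3, 3, 10, 10), doses = levels))
  res <- runCalibrate(cfg, quiet = TRUE)
  # oracle: recompute the aggregation for one dose level by hand
  films <- lapply(unlist(levels[[3]]$films), readTiffFilm, dpi = 25.4)
  reps <- lapply(films, function(f) {
    s <- roiStatistics(f, c(3, 3, 10, 10))
    pvmax <- 65535
    list(netT = unname(s$meanPv["R"]) / pvmax - 1,
         sig = unname(s$sdPv["R"]) / pvmax)
  })
  w <- 1 / c(reps[[1]]$sig, reps[[2]]$sig)^2
  manual <- sum(w * c(reps[[1]]$netT, reps[[2]]$netT)) / sum(w)
  # the fitted model evaluated at the aggregated response returns the dose
  expect_equal(predictDose(res$models$R, manual), 5, tolerance = 0.1)
})

test_that("calibration refuses missing films and short dose tables", {
  cfg <- list(calibration = list(
    model = "rational", roi = c(1, 1, 4, 4), dpi = 25.4,
    doses = list(list(dose_gy = 0, films = list("/nonexistent/a.tif")),
                 list(dose_gy = 2, films = list("/nonexistent/b.tif")),
                 list(dose_gy = 5, films = list("/nonexistent/c.tif")),
                 list(dose_gy = 8, films = list("/nonexistent/d.tif")))))
  expect_error(runCalibrate(cfg, quiet = TRUE), "/nonexistent/a.tif")
  cfg$calibration$doses <- cfg$calibration$doses[1:2]
  expect_error(runCalibrate(cfg, quiet = TRUE), "4 dose levels")
})

test_that("the comparison pipeline passes its own plan at 3%/3 mm", {
  dir <- tempfile("cmp")
  plan <- makeDosePhantom("uniform_square", doseGy = 5, fieldSizeMm = 80,
                          gridSpacingMm = 1, marginMm = 15)
  film <- filmFromDose(plan, fixtureModels, scannerNoiseSpec(seed = 61))
  cfg <- list(output_dir = dir, film = film, plan = plan,
              models = fixtureModels,
              reconstruction = list(method = "single", channel = "R",
                                    median_size = 1L, wiener_window = 1L),
              registration = list(flip_vertical = FALSE, rotate_180 = FALSE),
              gamma = list(dd = 3, dta = 3, threshold = 5,
                           normalization = "global"))
  res <- runCompare(cfg, quiet = TRUE)
  expect_equal(passRate(res$gamma), 1)
  expect_equal(res$registration@offsetPx, c(1L, 1L))
  report <- jsonlite::read_json(res$reportPath, simplifyVector = TRUE)
  expect_equal(report$pass_rate, 1)
  expect_equal(report$criteria$dd_percent, 3)
  expect_equal(report$criteria$normalization, "global")
  expect_true(file.exists(res$gammaPath))
  # gamma map re-reads as a valid dose grid
  gm <- readRTDose(res$gammaPath)
  expect_identical(dim(doseGrid(gm)), dim(doseGrid(plan)))
})

test_that("a 10% dose scaling fails plateau pixels exactly as the oracle says", {
  plan <- makeDosePhantom("uniform_square", doseGy = 5, fieldSizeMm = 60,
                          gridSpacingMm = 2, marginMm = 10)
  scaled <- DoseMap(doseGrid(plan) * 1.10, pixelSpacing(plan))
  res <- gammaMatrix(plan, scaled, gammaCriteria(3, 3, 5, "global"))
  expect_lt(passRate(res), 1)
  oracle <- gammaBrute(doseGrid(plan), doseGrid(scaled), c(2, 2), 3, 3,
                       thresholdPercent = 5)
  ok <- !is.na(oracle)
  expect_equal(sum(oracle[ok] <= 1) / sum(ok), passRate(res),
               tolerance = 1e-12)
})

test_that("run configs are validated and round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("gamma:", "  dd: 3", "  dta: 3", "output_dir: /tmp/x"), f)
  cfg <- readRunConfig(f)
  expect_equal(cfg$gamma$dd, 3)
  writeLines(c("paths:", "  film: /nonexistent/f.tif"), f)
  expect_error(readRunConfig(f), "/nonexistent/f.tif")
  expect_error(readRunConfig(tempfile()), "not found")
})

test_that("registration below the score floor advises a manual override", {
  plan <- makeDosePhantom("uniform_square", doseGy = 5, fieldSizeMm = 60,
                          gridSpacingMm = 2, marginMm = 10)
  film <- filmFromDose(plan, fixtureModels, scannerNoiseSpec(seed = 81))
  cfg <- list(output_dir = tempfile(), film = film, plan = plan,
              models = fixtureModels,
              reconstruction = list(method = "single", channel = "R",
                                    median_size = 1L, wiener_window = 1L),
              registration = list(flip_vertical = FALSE, rotate_180 = FALSE,
                                  min_score = 1.1),
              gamma = list(dd = 3, dta = 3))
  expect_error(runCompare(cfg, quiet = TRUE), "manual_offset")
  # manual override bypasses matching entirely
  cfg$registration$manual_offset <- c(1L, 1L)
  res <- runCompare(cfg, quiet = TRUE)
  expect_equal(passRate(res$gamma), 1)
})

test_that("the command-line interface writes a synthetic QA case", {
  cli <- system.file("cli", "filmdose.R", package = "filmdose")
  expect_true(nzchar(cli))
  out <- tempfile("synthcli")
  log <- suppressWarnings(system2("Rscript",
    c(cli, "synth", "--kind", "square", "--out", out, "--seed", "3",
      "--field", "60", "--spacing", "2"), stdout = TRUE, stderr = TRUE))
  expect_true(file.exists(file.path(out, "plan.dcm")))
  expect_true(file.exists(file.path(out, "film.tif")))
  expect_true(file.exists(file.path(out, "truth.json")))
  plan <- readRTDose(file.path(out, "plan.dcm"))
  expect_equal(max(doseGrid(plan)), 5, tolerance = 1e-3)
})
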