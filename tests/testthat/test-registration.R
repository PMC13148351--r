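# Orientation pre-processing, normalized cross-correlation, template
# matching with rotation sweep, matched-region cropping.

test_that("orientation pre-processing applies flip then 180-rotation", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE)  # [[1,2,3],[4,5,6]]
  expect_identical(preprocessFilm(m, FALSE, FALSE), m)
  expect_identical(preprocessFilm(preprocessFilm(m, TRUE, FALSE),
                                  TRUE, FALSE), m)
  # hand bookkeeping: flip rows -> [[4,5,6],[1,2,3]]; rotate 180 ->
  # [[3,2,1],[6,5,4]]
  expect_identical(preprocessFilm(m, TRUE, TRUE),
                   matrix(c(3, 2, 1, 6, 5, 4), 2, 3, byrow = TRUE))
  expect_identical(preprocessFilm(m, FALSE, TRUE),
                   matrix(c(6, 5, 4, 3, 2, 1), 2, 3, byrow = TRUE))
})

test_that("NCC map matches the literal double-loop evaluation", {
  set.seed(19)
  for (trial in 1:5) {
    image <- matrix(runif(32 * 32), 32, 32)
    template <- matrix(runif(8 * 8), 8, 8)
    expect_lt(max(abs(nccMap(template, image) - nccBrute(template, image))),
              1e-10)
  }
})

test_that("NCC peaks at 1 for exact and affine-intensity copies", {
  set.seed(23)
  image <- matrix(runif(40 * 40), 40, 40)
  template <- image[11:22, 8:19]
  sc <- nccMap(template, image)
  peak <- which(sc == max(sc), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(11, 8))
  expect_equal(max(sc), 1, tolerance = 1e-12)
  # invariance to affine intensity changes of either input
  sc2 <- nccMap(2 * template + 5, image)
  expect_equal(max(sc2), 1, tolerance = 1e-12)
  expect_lt(max(abs(sc2 - sc)), 1e-10)
  expect_error(nccMap(matrix(1, 4, 4), image), "zero-variance")
  # zero-variance windows score 0 instead of erroring
  flat <- matrix(0, 20, 20); flat[8:12, 8:12] <- 1
  scores <- nccMap(flat[8:12, 8:12, drop = FALSE] - 0.5 +
                     matrix(seq(0, 1e-9, length.out = 25), 5, 5), flat)
  expect_true(all(is.finite(scores)))
})

test_that("template matching recovers known embeddings across the sweep", {
  plan <- makeDosePhantom("pyramid", doseGy = c(2, 4, 6), fieldSizeMm = 80,
                          gridSpacingMm = 1, marginMm = 5)
  for (ang in c(0, 2, -3)) {
    case <- makeRegistrationCase(plan, offsetPx = c(26, 34), angleDeg = ang,
                                 noise = scannerNoiseSpec(seed = 40 + ang),
                                 canvasPx = c(150, 160))
    rec <- singleChannelDose(case$film, fixtureModels$R)
    res <- matchTemplate(plan, rec)
    expect_equal(res@angleDeg, ang)
    expect_lte(max(abs(res@offsetPx - case$truth$offsetPx)), 1)
    expect_lte(res@nccScore, 1 + 1e-9)
    expect_equal(res@nccScore, max(res@scoreMap))
  }
})

test_that("matching survives 20 dB additive noise", {
  plan <- makeDosePhantom("pyramid", doseGy = c(2, 4, 6), fieldSizeMm = 80,
                          gridSpacingMm = 1, marginMm = 5)
  case <- makeRegistrationCase(plan, offsetPx = c(26, 34), angleDeg = -3,
                               noise = scannerNoiseSpec(seed = 77),
                               canvasPx = c(150, 160))
  rec <- singleChannelDose(case$film, fixtureModels$R)
  set.seed(78)
  sigma <- sqrt(mean(doseGrid(rec)^2)) / 10^(20 / 20)   # SNR 20 dB
  noisy <- DoseMap(pmax(doseGrid(rec) +
                          matrix(rnorm(length(doseGrid(rec)), 0, sigma),
                                 nrow(doseGrid(rec))), 0),
                   pixelSpacing(rec))
  res <- matchTemplate(plan, noisy)
  expect_equal(res@angleDeg, -3)
  expect_lte(max(abs(res@offsetPx - c(26, 34))), 1)
})

test_that("cropping returns the matched region in the plan frame", {
  plan <- makeDosePhantom("uniform_square", doseGy = 5, fieldSizeMm = 60,
                          gridSpacingMm = 1, marginMm = 10)
  film <- DoseMap(matrix(0, 120, 130), c(1, 1))
  film@dose[21:(20 + nrow(doseGrid(plan))), 31:(30 + ncol(doseGrid(plan)))] <-
    doseGrid(plan)
  res <- matchTemplate(plan, film, anglesDeg = 0)
  crop <- cropMatched(film, res, dim(doseGrid(plan)))
  expect_identical(doseGrid(crop), doseGrid(plan))
  # idempotence: cropping the crop at zero offset changes nothing
  res0 <- new("RegistrationResult", offsetPx = c(1L, 1L), angleDeg = 0,
              nccScore = 1, scoreMap = matrix(1, 1, 1), anglesTried = 0)
  expect_identical(doseGrid(cropMatched(crop, res0, dim(doseGrid(crop)))),
                   doseGrid(crop))
  expect_error(cropMatched(crop, res, dim(doseGrid(plan)) + 100), "bounds")
})

test_that("rotated embedding round-trips through match + crop", {
  plan <- makeDosePhantom("pyramid", doseGy = c(2, 4, 6), fieldSizeMm = 80,
                          gridSpacingMm = 1, marginMm = 8)
  case <- makeRegistrationCase(plan, offsetPx = c(21, 26), angleDeg = 2,
                               noise = scannerNoiseSpec(seed = 55),
                               canvasPx = c(140, 150))
  rec <- singleChannelDose(case$film, fixtureModels$R)
  res <- matchTemplate(plan, rec)
  crop <- cropMatched(rec, res, dim(doseGrid(plan)))
  expect_lt(mean(abs(doseGrid(crop) - doseGrid(plan))),
            0.02 * max(doseGrid(plan)))
})
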