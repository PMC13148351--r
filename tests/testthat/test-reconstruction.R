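# Single-channel and multichannel dose reconstruction.

# Channel-consistent film with NO scanner quantization: pixel values kept
# real-valued so the three channels agree exactly at t = 1.
exactFilm <- function(dose, models = fixtureModels, pert = 1) {
  px <- array(0, c(dim(dose@dose), 3))
  for (k in 1:3) {
    r <- invertDose(models[[k]], dose@dose)
    od <- -log10(1 + r) * pert
    px[, , k] <- 65535 * 10^(-od)
  }
  ScannedFilm(px, 16L, pixelSpacing(dose))
}

test_that("single-channel reconstruction inverts the forward model", {
  plan <- makeDosePhantom("uniform_square", doseGy = 5, fieldSizeMm = 60,
                          gridSpacingMm = 2, marginMm = 10)
  film <- exactFilm(plan)
  rec <- singleChannelDose(film, fixtureModels$R)
  expect_lt(max(abs(doseGrid(rec) - doseGrid(plan))), 1e-9)
  expect_equal(pixelSpacing(rec), pixelSpacing(plan))
  # unirradiated film maps to zero dose
  blank <- ScannedFilm(array(65535, c(4, 4, 3)), 16L, c(1, 1))
  expect_identical(doseGrid(singleChannelDose(blank, fixtureModels$R)),
                   matrix(0, 4, 4))
  expect_error(singleChannelDose(film, fixtureModels$R, channel = "G"),
               "mismatch")
})

test_that("quantized forward model is inverted to within the count bound", {
  plan <- makeDosePhantom("uniform_square", doseGy = 5, fieldSizeMm = 60,
                          gridSpacingMm = 2, marginMm = 10)
  film <- filmFromDose(plan, fixtureModels, scannerNoiseSpec(seed = 4))
  rec <- singleChannelDose(film, fixtureModels$R)
  # bound: max model slope |dD/dnetT| <= |A| times half a 16-bit count
  bound <- 20 * 0.5 / 65535
  expect_lt(max(abs(doseGrid(rec) - doseGrid(plan))), bound * 1.01)
})

test_that("single-channel dose noise follows the delta method", {
  plan <- DoseMap(matrix(5, 30, 30), c(1, 1))
  film <- filmFromDose(plan, fixtureModels,
                       scannerNoiseSpec(gaussianSigmaFraction = 0.005,
                                        seed = 21))
  rec <- singleChannelDose(film, fixtureModels$R)
  expect_lt(abs(mean(doseGrid(rec)) - 5) / 5, 0.01)
  # sigma_D ~ |dD/dr| * sigma_r at 5 Gy for the red model
  p <- modelParams(fixtureModels$R)
  r5 <- 5 / (p["A"] + p["B"] * 5)
  slope <- abs(p["A"] / (1 - p["B"] * r5)^2)
  sigmaR <- 0.005 * (1 + r5)        # PV fraction on the transmittance scale
  expected <- unname(slope * sigmaR)
  expect_lt(abs(sd(as.vector(doseGrid(rec))) - expected) / expected, 0.15)
})

test_that("multichannel t is exactly 1 on channel-consistent films", {
  plan <- makeDosePhantom("uniform_square", doseGy = 5, fieldSizeMm = 60,
                          gridSpacingMm = 2, marginMm = 10)
  film <- exactFilm(plan)
  mc <- multichannelDose(film, fixtureModels)
  expect_lt(max(abs(tMap(mc) - 1)), 1e-6)
  expect_true(all(mc@converged))
  # with zero disturbance and zero noise the dose equals single-channel
  sc <- singleChannelDose(film, fixtureModels$R)
  expect_lt(max(abs(doseGrid(mc) - doseGrid(sc))), 1e-9)
})

test_that("a uniform multiplicative OD disturbance is recovered as 1/s", {
  plan <- DoseMap(matrix(5, 8, 8), c(1, 1))
  film <- exactFilm(plan, pert = 1.05)
  mc <- multichannelDose(film, fixtureModels)
  expect_true(all(mc@converged))
  expect_lt(max(abs(tMap(mc) - 1 / 1.05)), 1e-5)
  expect_lt(max(abs(doseGrid(mc) - 5)), 1e-6)
})

test_that("Newton t matches the dense grid-search oracle", {
  plan <- makeDosePhantom("uniform_square", doseGy = 5, fieldSizeMm = 50,
                          gridSpacingMm = 2, marginMm = 6)
  film <- filmFromDose(plan, fixtureModels,
                       scannerNoiseSpec(disturbanceAmplitude = 0.05,
                                        seed = 13))
  mc <- multichannelDose(film, fixtureModels)
  odf <- sapply(1:3, function(k) as.vector(odOfChannel(film, k)))
  set.seed(17)
  candidates <- which(as.vector(doseGrid(plan)) > 0.5 & as.vector(mc@converged))
  pick <- sample(candidates, 40)
  for (i in pick) {
    tOracle <- gridSearchTmin(odf[i, ], c(0, 0, 0), fixtureModels)
    expect_lt(abs(as.vector(tMap(mc))[i] - tOracle), 1e-4 + 1e-9)
  }
})

test_that("optimization never worsens channel agreement", {
  plan <- makeDosePhantom("uniform_square", doseGy = 5, fieldSizeMm = 50,
                          gridSpacingMm = 2, marginMm = 6)
  film <- filmFromDose(plan, fixtureModels,
                       scannerNoiseSpec(gaussianSigmaFraction = 0.003,
                                        disturbanceAmplitude = 0.03,
                                        seed = 29))
  mc <- multichannelDose(film, fixtureModels)
  odf <- sapply(1:3, function(k) as.vector(odOfChannel(film, k)))
  g <- function(tt, od) {
    D <- sapply(1:3, function(k) {
      p <- modelParams(fixtureModels[[k]])
      r <- 10^(-od[k] * tt) - 1
      p[1] * r / (1 - p[2] * r)
    })
    (D[1] - D[2])^2 + (D[1] - D[3])^2 + (D[2] - D[3])^2
  }
  set.seed(5)
  for (i in sample(length(tMap(mc)), 50))
    expect_lte(g(as.vector(tMap(mc))[i], odf[i, ]),
               g(1, odf[i, ]) + 1e-15)
})

test_that("multichannel suppresses disturbance noise relative to red channel", {
  plan <- DoseMap(matrix(5, 24, 24), c(2, 2))
  film <- filmFromDose(plan, fixtureModels,
                       scannerNoiseSpec(disturbanceAmplitude = 0.05,
                                        seed = 31))
  mc <- multichannelDose(film, fixtureModels)
  sc <- singleChannelDose(film, fixtureModels$R)
  expect_lte(var(as.vector(doseGrid(mc))), var(as.vector(doseGrid(sc))))
})

test_that("pixels with no interior minimum are flagged, not filled silently", {
  # channel ODs in inconsistent proportion at tiny dose: the pairwise
  # objective decreases monotonically toward t -> 0, so no interior
  # minimum exists on the trusted interval
  px <- array(65535, c(2, 2, 3))
  px[, , 1] <- 65500; px[, , 2] <- 65533; px[, , 3] <- 65534
  film <- ScannedFilm(px, 16L, c(1, 1))
  mc <- multichannelDose(film, fixtureModels)
  expect_true(any(!mc@converged))
  # flagged pixels carry the red-channel fallback dose, not a hole
  sc <- singleChannelDose(film, fixtureModels$R)
  bad <- !mc@converged
  expect_equal(doseGrid(mc)[bad], doseGrid(sc)[bad])
  expect_error(multichannelDose(film, fixtureModels[1:2]), "per channel")
})
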