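# Forward models, seeding law and rendering of the synthetic assay generator.

test_that("oxygen forward model follows the Stern-Volmer drawdown", {
  cfg <- simConfig(nFrames = 25, purgeFrames = 0, photoDrift = 0)

  # no consumption: constant intensity at I0 / ratio
  tr0 <- forwardOxygenTrace(0, cfg, sealed = TRUE)
  expect_equal(diff(range(tr0$intensity)), 0)
  expect_equal(tr0$intensity[1], cfg@baseCounts)

  # full depletion reproduces the calibration fold increase
  tr <- forwardOxygenTrace(0.8, cfg, sealed = TRUE)
  expect_equal(tr$intensity[25] / tr$intensity[1], 2.7, tolerance = 1e-12)

  # depletion time: (200 uM x 64.5 pL) / 0.8 fmol/min = 16.125 min
  fine <- forwardOxygenTrace(0.8, cfg, times = seq(0, 20, by = 0.125))
  expect_equal(min(fine$time[fine$o2Um == 0]), 16.125)

  # conservation: linear drawdown at the configured rate, then plateau
  rate <- 1000 * 0.8 / 64.5
  pre <- fine$time < 16.125
  expect_equal(fine$o2Um[pre], 200 - rate * fine$time[pre], tolerance = 1e-9)
  expect_true(all(fine$o2Um[!pre] == 0))

  # monotonicity of the sealed occupied-well intensity
  expect_true(all(diff(tr$intensity) >= 0))
})

test_that("unsealed wells exchange oxygen with the ambient medium", {
  cfg <- simConfig(nFrames = 40, purgeFrames = 10, photoDrift = 0)
  leaky <- forwardOxygenTrace(0.8, cfg, sealed = FALSE)
  sealed <- forwardOxygenTrace(0.8, cfg, sealed = TRUE)
  # a leaky well never fully depletes: it approaches a steady state above 0
  expect_gt(min(leaky$o2Um[1:40]), 0)
  # during the purge the sealed well holds; the leaky well is quenched
  expect_equal(diff(range(sealed$intensity[41:50])), 0)
  expect_lt(leaky$intensity[50], 0.5 * leaky$intensity[40])
  expect_gt(leaky$o2Um[50], cfg@oAirUm)  # moving toward the purge level
})

test_that("configuration invariants are enforced", {
  expect_error(simConfig(wellVolumePl = 0), "wellVolumePl")
  expect_error(simConfig(o2Ratio = 1), "o2Ratio")
  expect_error(simConfig(leakFraction = 1.2), "leakFraction")
  expect_error(simConfig(phParams = c(i1 = 0.2, i2 = 1, pKa = 7, theta = 1)),
               "i1")
  expect_error(simConfig(phParams = c(i1 = 1.3, i2 = 0.3, pKa = 7,
                                      theta = -1)), "theta")
})

test_that("pH forward model is sigmoid-consistent and invertible", {
  cfg <- simConfig(nFrames = 20, purgeFrames = 0)
  tr0 <- forwardPhTrace(0, cfg)
  expect_equal(diff(range(tr0$intensity)), 0)

  # pH falling 7.4 -> 6.4: strictly decreasing intensity
  tr <- forwardPhTrace(0.05, cfg)
  expect_equal(tr$ph, pmax(6.0, 7.4 - 0.05 * tr$time))
  expect_true(all(diff(tr$intensity) < 0))

  # noise-free round trip through the model inverse
  cal <- new("PHCalibration",
             i1 = cfg@phParams[["i1"]], i2 = cfg@phParams[["i2"]],
             pKa = cfg@phParams[["pKa"]], theta = cfg@phParams[["theta"]],
             iRef = 1, rms = 0)
  phBack <- phTraceToPh(tr$intensity, cal, mediumPh = cfg@phStart)
  expect_lt(max(abs(as.numeric(phBack) - tr$ph)), 1e-9)
})

test_that("cell seeding is truncated-Poisson and deterministic", {
  expect_identical(seedCells(simConfig(gridRows = 5, gridCols = 5,
                                       seedingMean = 0)), integer(25))

  cfg <- simConfig(gridRows = 100, gridCols = 100, seedingMean = 0.4,
                   rngSeed = 42)
  k <- seedCells(cfg)
  expect_true(all(k >= 0 & k <= cfg@maxCellsPerWell))
  p1 <- 0.4 * exp(-0.4)
  se <- sqrt(p1 * (1 - p1) / length(k))
  expect_lt(abs(mean(k == 1) - p1), 3 * se)

  expect_identical(k, seedCells(cfg))
})

test_that("rendering is deterministic and repeats frames for static wells", {
  cfg <- simConfig(gridRows = 4, gridCols = 4, nFrames = 5, purgeFrames = 0,
                   seedingMean = 0, noiseCv = 0, readNoise = 0,
                   photoDrift = 0, leakFraction = 0, defectFraction = 0,
                   driftPxPerFrame = 0, rngSeed = 9)
  sim <- renderAssay(cfg, nuclei = FALSE)
  for (t in 2:5)
    expect_identical(sim@stacks$ref[, , t], sim@stacks$ref[, , 1])
  expect_identical(sim@stacks$o2[, , 5], sim@stacks$o2[, , 1])

  sim2 <- renderAssay(cfg, nuclei = FALSE)
  expect_identical(groundTruth(sim), groundTruth(sim2))
  expect_identical(sim@stacks$o2, sim2@stacks$o2)
})

test_that("defect flags and rendered malformations are consistent", {
  cfg <- simConfig(gridRows = 8, gridCols = 8, nFrames = 2, purgeFrames = 0,
                   seedingMean = 0, noiseCv = 0, gainFieldAmp = 0,
                   leakFraction = 0, defectFraction = 0.1, rngSeed = 5)
  sim <- renderAssay(cfg, nuclei = FALSE)
  tr <- groundTruth(sim)
  expect_gt(sum(tr$defective), 0)
  img <- sim@stacks$ref[, , 1]
  h <- nrow(img)
  # defective wells have a sensor void: dark interior at the well center
  for (i in seq_len(nrow(tr))) {
    centerVal <- img[round(tr$y[i]) + 1, round(tr$x[i]) + 1]
    if (tr$defective[i]) expect_lt(centerVal, 500)
    else expect_gt(centerVal, 900)
  }
})

test_that("ground truth obeys its invariants", {
  cfg <- simConfig(gridRows = 10, gridCols = 10, nFrames = 2,
                   purgeFrames = 0, seedingMean = 0.5, rngSeed = 2)
  tr <- groundTruth(renderAssay(cfg, nuclei = FALSE))
  empty <- tr$cellCount == 0
  expect_true(all(tr$trueOcr[empty] == 0))
  expect_true(all(tr$trueEcar[empty] == 0))
  expect_true(all(tr$trueOcr[!empty] > 0))
})

test_that("calibration series: midpoint, linear band and fit round trip", {
  p <- c(i1 = 1.35, i2 = 0.27, pKa = 7, theta = 1)
  # sigmoid midpoint identity
  expect_equal(phSigmoid(7, p), (1.35 + 0.27) / 2)

  # near-linear response over the working band 6.4-7.4
  band <- seq(6.4, 7.4, by = 0.05)
  iv <- phSigmoid(band, p)
  fit <- lm(iv ~ band)
  expect_lt(max(abs(residuals(fit))), 0.05 * (1.35 - 0.27))

  # noise-free grid round trip through the sigmoid fit
  cal <- makeCalibrationSeries(p, seq(3, 9, length.out = 13))
  fitCal <- fitPhSigmoid(cal$ph, cal$intensity, mediumPh = 7.4)
  anchor <- phSigmoid(7.4, p)
  expect_equal(fitCal@i1, 1.35 / anchor, tolerance = 1e-6)
  expect_equal(fitCal@i2, 0.27 / anchor, tolerance = 1e-6)
  expect_equal(fitCal@pKa, 7, tolerance = 1e-6)
  expect_equal(fitCal@theta, 1, tolerance = 1e-6)

  expect_error(makeCalibrationSeries(p, numeric(0)), "empty")
  expect_error(makeCalibrationSeries(p, c(3, 15)), "0-14")
})

test_that("assays round-trip through plain-file serialization", {
  cfg <- simConfig(gridRows = 4, gridCols = 4, nFrames = 3, purgeFrames = 0,
                   seedingMean = 0.4, rngSeed = 4)
  sim <- renderAssay(cfg)
  dir <- tempfile("assay")
  writeAssay(sim, dir)
  back <- readAssay(dir)
  expect_equal(back$truth$cellCount, groundTruth(sim)$cellCount)
  expect_equal(back$times, sim@times)
  # 16-bit quantization bounds the intensity error
  top <- max(sim@stacks$ref)
  expect_lt(max(abs(back$stacks$ref - sim@stacks$ref)), top / 65535 * 1.01)
  unlink(dir, recursive = TRUE)
})

test_that("config files round-trip through YAML", {
  cfg <- simConfig(gridRows = 7, ocrMedian = 0.46, rngSeed = 77)
  path <- tempfile(fileext = ".yaml")
  writeSimConfig(cfg, path)
  back <- readSimConfig(path)
  expect_equal(back@gridRows, 7L)
  expect_equal(back@ocrMedian, 0.46)
  expect_equal(back@phParams, cfg@phParams)
  unlink(path)
})
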