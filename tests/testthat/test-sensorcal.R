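# Stern-Volmer oxygen calibration and the sigmoid pH model.

test_that("two-point calibration reproduces the quenching constant", {
  cal <- fitO2TwoPoint(iAir = 1000, i0 = 2700, oAirUm = 200)
  expect_equal(cal@kSv, 1.7 / 200)          # 0.0085 1/uM
  expect_equal(fitO2TwoPoint(500, 500, 200)@kSv, 0)
  expect_error(fitO2TwoPoint(1000, 900), "I0 >= I_air")

  # forward-generate the two points from random constants: exact recovery
  set.seed(61)
  for (rep in 1:10) {
    k <- runif(1, 0.001, 0.05); i0 <- runif(1, 500, 5000)
    iAir <- i0 / (1 + k * 200)
    expect_equal(fitO2TwoPoint(iAir, i0, 200)@kSv, k, tolerance = 1e-12)
  }
})

test_that("intensity-to-oxygen inversion is exact and monotone", {
  cal <- fitO2TwoPoint(1000, 2700, 200)
  expect_equal(as.numeric(intensityToOxygen(2700, cal)), 0)
  expect_equal(as.numeric(intensityToOxygen(2700 / 2.7, cal)), 200,
               tolerance = 1e-9)

  cfg <- simConfig(nFrames = 30, purgeFrames = 0, photoDrift = 0)
  fw <- forwardOxygenTrace(0.5, cfg)
  back <- intensityToOxygen(fw$intensity,
                            fitO2TwoPoint(cfg@baseCounts,
                                          cfg@baseCounts * 2.7, 200))
  expect_lt(max(abs(as.numeric(back) - fw$o2Um)), 1e-9)

  grid <- seq(500, 2699, length.out = 50)
  o2 <- as.numeric(intensityToOxygen(grid, cal))
  expect_true(all(diff(o2) < 0))  # strictly decreasing in I

  expect_error(intensityToOxygen(100, fitO2TwoPoint(500, 500, 200)),
               "not invertible")
  # intensities above I0 clip to zero with a flag
  clipped <- intensityToOxygen(c(2800, 1000), cal)
  expect_equal(as.numeric(clipped)[1], 0)
  expect_true(attr(clipped, "clipped")[1])
  expect_false(attr(clipped, "clipped")[2])
})

test_that("the Stern-Volmer ratio is exactly linear in oxygen", {
  k <- 0.0085; i0 <- 2700
  o2 <- seq(0, 200, by = 10)
  I <- i0 / (1 + k * o2)
  fit <- lm(y ~ o2, data = data.frame(y = i0 / I - 1, o2 = o2))
  expect_equal(unname(coef(fit)[2]), k, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("local calibration recovers the generator constant from plateaued
           wells and averages over completers", {
  cfg <- simConfig(nFrames = 50, purgeFrames = 0, photoDrift = 0)
  # noise-free single well with an exact plateau
  m <- makeTraceMatrix(0.8, cfg)
  lc <- localO2Calibration(m, (0:49) * 1, oAirUm = 200)
  expect_true(lc$perWell$completed[1])
  expect_equal(lc$perWell$kSv[1], 0.0085, tolerance = 1e-9)
  expect_equal(lc$average@kSv, 0.0085, tolerance = 1e-9)

  # all wells share the constant: the assay average equals it exactly
  m3 <- makeTraceMatrix(c(0.5, 0.8, 1.2), cfg)
  lc3 <- localO2Calibration(m3, (0:49) * 1, oAirUm = 200)
  expect_equal(lc3$average@kSv, 0.0085, tolerance = 1e-9)

  # the average is applied to wells that never complete (and empty wells)
  m4 <- makeTraceMatrix(c(0.8, 0.05, 0), cfg)
  lc4 <- localO2Calibration(m4, (0:49) * 1, oAirUm = 200)
  expect_false(lc4$perWell$completed[3])
  expect_equal(lc4$perWell$kSv[3], lc4$average@kSv)

  # 2% region-level noise: the assay average stays within 5% of truth
  set.seed(62)
  ocrs <- rlnorm(40, log(0.8), log(1.6))
  mN <- makeTraceMatrix(ocrs, cfg, noiseSd = 0.02, seed = 63)
  lcN <- localO2Calibration(mN, (0:49) * 1, oAirUm = 200)
  expect_lt(abs(lcN$average@kSv - 0.0085) / 0.0085, 0.05)

  expect_error(localO2Calibration(makeTraceMatrix(0, cfg), (0:49) * 1,
                                  oAirUm = 200), "no wells completed")
})

test_that("sigmoid fit recovers parameters and its inverse round-trips", {
  p <- c(i1 = 1.35, i2 = 0.27, pKa = 7, theta = 1)
  cal <- fitPhSigmoid(seq(3, 9, by = 0.5),
                      phSigmoid(seq(3, 9, by = 0.5), p), mediumPh = 7.4)
  # midpoint identity on the fitted curve
  expect_equal(phSigmoid(cal@pKa, cal), (cal@i1 + cal@i2) / 2,
               tolerance = 1e-12)

  # closed-form inversion: midpoint maps to pKa, grid round-trips to 1e-9
  expect_equal(as.numeric(intensityToPh((cal@i1 + cal@i2) / 2, cal)),
               cal@pKa, tolerance = 1e-9)
  grid <- seq(3, 9, by = 0.25)
  back <- intensityToPh(phSigmoid(grid, cal), cal)
  expect_lt(max(abs(as.numeric(back) - grid)), 1e-9)

  # boundary behavior: slight overshoot clamps with a flag, gross errors stop
  nearTop <- cal@i1 + 0.001 * (cal@i1 - cal@i2)
  res <- intensityToPh(nearTop, cal, tol = 0.02)
  expect_true(attr(res, "clamped")[1])
  expect_true(is.finite(as.numeric(res)))
  expect_error(intensityToPh(cal@i1 * 1.5, cal), "dynamic range")

  expect_error(fitPhSigmoid(c(6, 7, 8), c(0.5, 0.7, 0.9)), "5 distinct")
})

test_that("the working band 6.4-7.4 is near-linear", {
  band <- seq(6.4, 7.4, by = 0.1)
  p <- c(i1 = 1.35, i2 = 0.27, pKa = 7, theta = 1)
  iv <- phSigmoid(band, p)
  expect_gt(summary(lm(iv ~ band))$r.squared, 0.99)
})

test_that("sigmoid parameter recovery stays accurate at 1% noise", {
  set.seed(64)
  relErr <- matrix(NA_real_, 100, 4)
  for (rep in 1:100) {
    truth <- c(i1 = runif(1, 1.1, 2), i2 = runif(1, 0.1, 0.6),
               pKa = runif(1, 6, 8), theta = runif(1, 0.7, 1.6))
    if (truth[["i2"]] >= truth[["i1"]]) next
    grid <- seq(3, 9, length.out = 15)
    iv <- phSigmoid(grid, truth) * (1 + 0.01 * rnorm(15))
    fit <- tryCatch(fitPhSigmoid(grid, iv, mediumPh = 7.4, nStarts = 4),
                    error = function(e) NULL)
    if (is.null(fit)) next
    anchor <- phSigmoid(7.4, truth)
    relErr[rep, ] <- abs(c(fit@i1 - truth[["i1"]] / anchor,
                           fit@i2 - truth[["i2"]] / anchor,
                           fit@pKa - truth[["pKa"]],
                           fit@theta - truth[["theta"]])) /
      abs(c(truth[["i1"]] / anchor, truth[["i2"]] / anchor,
            truth[["pKa"]], truth[["theta"]]))
  }
  med <- apply(relErr, 2, median, na.rm = TRUE)
  expect_true(all(med < 0.05))
})

test_that("pH inversion is strictly increasing in intensity", {
  cal <- new("PHCalibration", i1 = 1.3, i2 = 0.26, pKa = 7, theta = 1,
             iRef = 1, rms = 0)
  iv <- seq(0.3, 1.25, length.out = 40)
  ph <- as.numeric(intensityToPh(iv, cal))
  expect_true(all(diff(ph) > 0))
})
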