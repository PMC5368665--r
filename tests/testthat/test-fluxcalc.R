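# Linear-window finding, OCR/ECAR regression and population statistics.

test_that("the linear window ends at the breakpoint of a line-plateau trace", {
  times <- 0:29
  bp <- 18
  series <- c(200 - 10 * times[1:bp], rep(200 - 10 * (bp - 1), 30 - bp))
  lw <- findLinearWindow(series, times)
  expect_lte(abs(lw$window[2] - bp), 1)
  expect_true(lw$plateauReached)
  expect_equal(lw$slope, -10, tolerance = 1e-6)

  # flat series: full window, slope ~ 0, no plateau (it never declined)
  flat <- rep(5, 20)
  lwF <- findLinearWindow(flat, 0:19)
  expect_equal(lwF$window, c(1L, 20L))
  expect_false(lwF$plateauReached)
  expect_equal(lwF$slope, 0)

  expect_error(findLinearWindow(1:5, 1:5), "at least 6")
})

test_that("breakpoints are found within 2 frames under 2% noise in at least
           90% of runs", {
  times <- 0:39
  bp <- 25
  hits <- 0
  set.seed(71)
  for (rep in 1:100) {
    clean <- c(200 - 7 * times[1:bp], rep(200 - 7 * (bp - 1), 40 - bp))
    noisy <- clean + 0.02 * 200 * rnorm(40)
    lw <- findLinearWindow(noisy, times)
    if (abs(lw$window[2] - bp) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("OCR matches hand arithmetic and an independent OLS oracle", {
  # constant oxygen: zero rate
  expect_equal(computeOcr(rep(150, 10), 0:9, 64.5, c(1, 10))$ocr, 0)

  # 200 -> 0 uM over 16.125 min in 64.5 pL: 0.80 fmol/min
  times <- 0:16
  o2 <- 200 - (200 / 16.125) * times
  est <- computeOcr(o2, times, 64.5, c(1, 17))
  expect_equal(est$ocr, 0.80, tolerance = 1e-9)

  # random noisy lines: slope and CI match stats::lm
  set.seed(72)
  for (rep in 1:5) {
    y <- 180 - 6 * (0:19) + rnorm(20, 0, 3)
    est <- computeOcr(y, 0:19, 64.5, c(1, 20))
    fit <- lm(y ~ t, data = data.frame(y = y, t = 0:19))
    slope <- unname(coef(fit)[2])
    se <- summary(fit)$coefficients[2, 2]
    expect_equal(est$ocr, -slope * 64.5 / 1000, tolerance = 1e-12)
    hw <- qt(0.975, 18) * se * 64.5 / 1000
    expect_equal(est$ciPercent, 100 * hw / abs(est$ocr), tolerance = 1e-9)
  }

  expect_error(computeOcr(c(1, NA, 3, 4, 5), 0:4, 64.5, c(1, 5)),
               "non-finite")
})

test_that("ECAR is the negative pH slope with positive sign for
           acidification", {
  expect_equal(computeEcar(rep(7.2, 8), 0:7, c(1, 8))$ecar, 0)

  # pH 7.4 -> 6.4 over 20 minutes: 0.05 pH/min
  times <- 0:20
  ph <- 7.4 - 0.05 * times
  expect_equal(computeEcar(ph, times, c(1, 21))$ecar, 0.05,
               tolerance = 1e-12)

  set.seed(73)
  y <- 7.4 - 0.03 * (0:19) + rnorm(20, 0, 0.01)
  est <- computeEcar(y, 0:19, c(1, 20))
  fit <- lm(y ~ t, data = data.frame(y = y, t = 0:19))
  expect_equal(est$ecar, -unname(coef(fit)[2]), tolerance = 1e-12)
})

test_that("rate estimators are unbiased on noise-free linear input", {
  times <- seq(0, 30, by = 1.5)
  o2 <- 200 - 4.4 * times
  expect_equal(computeOcr(o2, times, 64.5, c(1, length(times)))$ocr,
               4.4 * 64.5 / 1000, tolerance = 1e-12)
  ph <- 7.4 - 0.021 * times
  expect_equal(computeEcar(ph, times, c(1, length(times)))$ecar, 0.021,
               tolerance = 1e-12)
})

test_that("empty-well background is the median effective OCR", {
  set.seed(74)
  bgs <- rnorm(20, 0.015, 0.003)
  bg <- estimateBackgroundOcr(bgs)
  expect_equal(bg$background, median(bgs))
  expect_equal(bg$n, 20)
  expect_error(estimateBackgroundOcr(c(0.01, 0.02)), "at least 5")
})

test_that("response classification separates empty, responding and flat
           wells", {
  expect_equal(classifyResponse(0, 0.5, 0.01, 0.01, 0.001), "empty")
  expect_equal(classifyResponse(1, 0.5, 0.01, 0.01, 0.001), "responding")
  expect_equal(classifyResponse(1, 0.001, 0.01, 0.0001, 0.001),
               "non_responding")
  # a strong ECAR alone is enough
  expect_equal(classifyResponse(2, 0.001, 0.01, 0.05, 0.001), "responding")
})

test_that("per-cell normalization divides by occupancy and flags singles", {
  rec <- data.frame(cellCount = c(1L, 4L, 0L),
                    ocr = c(0.5, 2.0, 0.01), ecar = c(0.01, 0.08, 0))
  out <- normalizePerCell(rec)
  expect_equal(out$perCellOcr, c(0.5, 0.5, NA))
  expect_equal(out$perCellEcar[2], 0.02)
  expect_equal(out$singleCell, c(TRUE, FALSE, FALSE))

  recBad <- data.frame(cellCount = 0L, ocr = 1, ecar = 0.1, occupied = TRUE)
  expect_error(normalizePerCell(recBad), "zero cell count")
})

test_that("the KS comparison equals a brute-force ECDF oracle", {
  set.seed(75)
  a <- rlnorm(30); b <- rlnorm(40, 0.5)
  cmp <- comparePopulations(a, b)
  # exhaustive max ECDF gap
  grid <- sort(c(a, b))
  gap <- max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g),
                        numeric(1))))
  expect_equal(cmp$ksStatistic, gap, tolerance = 1e-12)

  same <- comparePopulations(a, a)
  expect_equal(same$ksStatistic, 0)
  expect_equal(same$foldChange, 1)

  # repeat the oracle on small random instances
  for (rep in 1:10) {
    x <- rnorm(sample(10:50, 1)); y <- rnorm(sample(10:50, 1), 0.3)
    gap <- max(abs(vapply(sort(c(x, y)), function(g)
      mean(x <= g) - mean(y <= g), numeric(1))))
    expect_equal(comparePopulations(x, y)$ksStatistic, gap,
                 tolerance = 1e-12)
  }

  expect_error(comparePopulations(numeric(0), a), "empty")
})

test_that("a 4.5-fold median difference is recovered from lognormal
           populations", {
  set.seed(76)
  a <- rlnorm(300, log(0.010), log(1.8))
  b <- rlnorm(300, log(0.045), log(1.8))
  cmp <- comparePopulations(a, b)
  expect_lt(abs(cmp$foldChange - 4.5) / 4.5, 0.15)
  expect_lt(cmp$pValue, 1e-10)
})

test_that("occupancy analysis: null case is quiet, sums tighten spread", {
  # identical per-cell law across occupancies: adjacent KS mostly quiet
  set.seed(77)
  quiet <- 0
  for (rep in 1:20) {
    rec <- data.frame(cellCount = rep(1:4, each = 30),
                      perCellOcr = rlnorm(120, log(0.5), log(1.6)),
                      perCellEcar = rlnorm(120, log(0.01), log(1.6)))
    oa <- occupancyAnalysis(rec, occupancies = 1:4)
    if (all(oa$adjacentKs$pOcr > 0.05)) quiet <- quiet + 1
  }
  expect_gte(quiet, 18)

  # per-cell rates from k-cell sums: IQR decreases with occupancy
  set.seed(78)
  recs <- do.call(rbind, lapply(1:5, function(k) {
    wells <- replicate(400, sum(rlnorm(k, log(0.5), log(1.8))))
    data.frame(cellCount = k, perCellOcr = wells / k,
               perCellEcar = wells / k * 0.02)
  }))
  oa2 <- occupancyAnalysis(recs, occupancies = 1:5)
  expect_true(all(diff(oa2$groups$iqrPerCellOcr) < 0))

  # single group: summaries only, no tests
  oa3 <- occupancyAnalysis(recs[recs$cellCount == 2, ], occupancies = 1:5)
  expect_null(oa3$adjacentKs)
  expect_equal(nrow(oa3$groups), 1)
})

test_that("normalization to basal medians reproduces known fold responses", {
  set.seed(79)
  basal <- rlnorm(200, log(0.8), log(1.5))
  fccp <- rlnorm(200, log(1.6), log(1.5))
  expect_equal(normalizeToBasal(fccp, basal), 2, tolerance = 0.25)
})
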