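# Detection chain: flattening, binarization, Hough detection, consolidation,
# grid filtering, tracking and similarity registration.

test_that("illumination flattening removes a known gain field", {
  img <- matrix(5, 120, 140)
  out <- flattenIllumination(img)
  expect_equal(mean(out), 1, tolerance = 1e-9)
  expect_equal(diff(range(out)), 0)

  # apply a smooth gain field and invert it
  xs <- seq(-1, 1, length.out = 140)
  ys <- seq(-1, 1, length.out = 120)
  gain <- 1 + 0.3 * outer(ys, xs) + 0.2 * outer(ys^2, xs * 0 + 1)
  out2 <- flattenIllumination(img * gain, method = "poly")
  expect_lt(max(abs(out2 - 1)), 0.02)
  expect_equal(mean(out2), 1, tolerance = 1e-9)
  # the heavy-blur estimate also suppresses the field away from edges
  out3 <- flattenIllumination(img * gain, sigmaPx = 30)
  inner <- out3[20:100, 20:120]
  expect_lt(max(abs(inner - 1)), 0.03)
  expect_equal(mean(out3), 1, tolerance = 1e-9)

  expect_error(flattenIllumination(matrix(0, 50, 50)), "constant-zero")
})

test_that("lip binarization matches the geometric area fraction", {
  cfg <- simConfig(gridRows = 6, gridCols = 6, nFrames = 1, purgeFrames = 0,
                   seedingMean = 0, noiseCv = 0, gainFieldAmp = 0,
                   leakFraction = 0, defectFraction = 0)
  sim <- renderAssay(cfg, nuclei = FALSE)
  lay <- sim@layout
  img <- sim@stacks$ref[, , 1]
  mask <- binarizeLips(img, lay)
  r <- lay@wellRadiusPx
  frac <- 36 * pi * r^2 * (1.15^2 - 0.88^2) / length(img)
  expect_lt(abs(mean(mask) - frac), 0.005)

  # invariance to global intensity scaling
  expect_identical(mask, binarizeLips(img * 7.3, lay))

  expect_error(binarizeLips(matrix(1, 50, 50), lay), "constant")
})

test_that("Hough detection finds a rendered circle where an exhaustive
           accumulator oracle puts it", {
  img <- matrix(0, 200, 200)
  cx <- 100; cy <- 100; r <- 12
  for (x in 0:199) for (y in 0:199) {
    d <- sqrt((x - cx)^2 + (y - cy)^2)
    if (abs(d - r) <= 1) img[y + 1, x + 1] <- 1
  }
  det <- detectCircles(img > 0, radii = 10:14)
  best <- det[which.max(det$confidence), ]
  expect_lt(sqrt((best$x - cx)^2 + (best$y - cy)^2), 1)

  # brute-force voting oracle at the true radius over a candidate grid
  pix <- which(img > 0)
  py <- (pix - 1) %% 200; px <- (pix - 1) %/% 200
  votes <- matrix(0, 21, 21)
  for (ix in 1:21) for (iy in 1:21) {
    ccx <- 90 + ix - 1; ccy <- 90 + iy - 1
    d <- sqrt((px - ccx)^2 + (py - ccy)^2)
    votes[iy, ix] <- sum(abs(d - r) <= 0.5)
  }
  oracle <- which(votes == max(votes), arr.ind = TRUE)[1, ]
  expect_equal(unname(90 + oracle["col"] - 1), 100)  # oracle agrees: x
  expect_equal(unname(90 + oracle["row"] - 1), 100)  # oracle agrees: y

  # blank mask gives an empty candidate list, not an error
  blank <- detectCircles(matrix(FALSE, 50, 50), radii = 5:8)
  expect_equal(nrow(blank), 0)
})

test_that("consolidation merges duplicates like single-linkage clustering", {
  one <- data.frame(x = 10, y = 20, confidence = 2, radiusPx = 5)
  out <- consolidateDetections(one, 6)
  expect_equal(out$x, 10); expect_equal(out$y, 20)
  expect_equal(out$confidence, 2)

  # two coincident candidates: confidence-weighted center, max confidence
  two <- data.frame(x = c(0, 4), y = c(0, 0), confidence = c(1, 3),
                    radiusPx = c(5, 5))
  m <- consolidateDetections(two, 6)
  expect_equal(nrow(m), 1)
  expect_equal(m$x, 3)        # (0*1 + 4*3) / 4
  expect_equal(m$confidence, 3)

  # random clusters agree with the exhaustive hclust single-linkage oracle
  set.seed(31)
  for (rep in 1:5) {
    n <- 60
    pts <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100),
                      confidence = runif(n, 0.5, 2), radiusPx = 5)
    cutoff <- 8
    out <- consolidateDetections(pts, cutoff)
    hc <- hclust(dist(pts[, c("x", "y")]), method = "single")
    cl <- cutree(hc, h = cutoff - 1e-9)
    oracle <- t(sapply(split(seq_len(n), cl), function(ix) {
      w <- pts$confidence[ix]
      c(x = sum(pts$x[ix] * w) / sum(w), y = sum(pts$y[ix] * w) / sum(w),
        conf = max(w))
    }))
    expect_equal(nrow(out), nrow(oracle))
    ordA <- order(out$x, out$y)
    ordB <- order(oracle[, "x"], oracle[, "y"])
    expect_equal(out$x[ordA], unname(oracle[ordB, "x"]), tolerance = 1e-9)
    expect_equal(out$y[ordA], unname(oracle[ordB, "y"]), tolerance = 1e-9)
    expect_equal(out$confidence[ordA], unname(oracle[ordB, "conf"]))
  }

  # idempotence
  again <- consolidateDetections(out, 8)
  expect_equal(nrow(again), nrow(out))
})

test_that("grid filtering keeps the lattice and discards spurious points", {
  lay <- arrayLayout(8, 8, 5, 25)
  centers <- expand.grid(r = 0:7, c = 0:7)
  pts <- data.frame(
    x = 30 + (centers$c + 0.5 * (centers$r %% 2)) * 25,
    y = 30 + centers$r * 25 * sqrt(3) / 2,
    confidence = 1)

  # perfect lattice: everything retained with consistent indices
  g <- enforceGrid(pts, lay)
  expect_equal(nrow(g), 64)
  expect_equal(sort(unique(g$row)), 0:7)
  expect_equal(sort(unique(g$col)), 0:7)
  expect_false(any(duplicated(paste(g$row, g$col))))
  ord <- order(g$y, g$x)
  expect_equal(g$row[ord], centers$r[order(pts$y, pts$x)])
  expect_equal(g$col[ord], centers$c[order(pts$y, pts$x)])

  # five spurious points die, the lattice survives
  set.seed(17)
  spur <- data.frame(x = runif(5, 40, 180), y = runif(5, 40, 130),
                     confidence = 0.6)
  # keep spurious points off lattice nodes
  spur$x <- spur$x + 9
  both <- rbind(pts, spur)
  g2 <- enforceGrid(both, lay)
  expect_equal(nrow(g2), 64)
  expect_true(all(g2$gridResidual < 25 / 4))

  # 2% jitter stays below the tolerance: all points retained
  set.seed(18)
  jit <- pts
  jit$x <- jit$x + rnorm(64, 0, 0.02 * 25)
  jit$y <- jit$y + rnorm(64, 0, 0.02 * 25)
  expect_equal(nrow(enforceGrid(jit, lay)), 64)

  expect_error(enforceGrid(pts[1:3, ], lay), "too few")
})

test_that("similarity transform matches the closed-form Procrustes solution", {
  A <- cbind(c(0, 1, 0, 2, 3), c(0, 0, 1, 2, 1))

  idt <- fitSimilarityTransform(A, A)
  expect_equal(idt@scale, 1, tolerance = 1e-12)
  expect_equal(idt@rotation, 0, tolerance = 1e-12)
  expect_equal(idt@translation, c(0, 0), tolerance = 1e-12)

  # pure scale + shift recovered to numerical precision
  B <- 2.5 * A + matrix(rep(c(10, -4), each = 5), ncol = 2)
  st <- fitSimilarityTransform(A, B)
  expect_equal(st@scale, 2.5, tolerance = 1e-9)
  expect_equal(st@rotation, 0, tolerance = 1e-9)
  expect_lt(st@rms, 1e-9)

  # reflected targets still produce an orientation-preserving fit
  Bref <- cbind(B[, 1], -B[, 2])
  rf <- fitSimilarityTransform(A, Bref)
  expect_gt(rf@scale, 0)
  th <- rf@rotation
  expect_equal(det(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)), 1,
               tolerance = 1e-12)

  expect_error(fitSimilarityTransform(matrix(1, 3, 2), matrix(2, 3, 2)),
               "coincident")

  # random instances: numerical-optimizer oracle reaches the same minimum
  set.seed(23)
  for (rep in 1:5) {
    n <- 3 + rep
    A <- matrix(rnorm(2 * n, sd = 10), ncol = 2)
    th <- runif(1, -pi, pi); s <- runif(1, 0.5, 3)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    B <- t(s * Rm %*% t(A)) + matrix(rep(rnorm(2), each = n), ncol = 2) +
      matrix(rnorm(2 * n, sd = 0.05), ncol = 2)
    fit <- fitSimilarityTransform(A, B)
    obj <- function(p) {
      Rp <- matrix(c(cos(p[2]), sin(p[2]), -sin(p[2]), cos(p[2])), 2, 2)
      pred <- t(exp(p[1]) * Rp %*% t(A)) + rep(p[3:4], each = n)
      mean(rowSums((B - pred)^2))
    }
    op <- optim(c(log(fit@scale), fit@rotation, fit@translation), obj,
                method = "BFGS")
    # closed form attains the optimizer's minimum
    expect_lte(fit@rms^2, op$value + 1e-8)
    expect_equal(fit@scale, exp(op$par[1]), tolerance = 1e-4)
  }
})

test_that("rigid tracking recovers injected shifts from a cropped subset", {
  cfg <- simConfig(gridRows = 8, gridCols = 8, nFrames = 6, purgeFrames = 0,
                   seedingMean = 0, noiseCv = 0.01, gainFieldAmp = 0,
                   leakFraction = 0, defectFraction = 0, photoDrift = 0,
                   rngSeed = 6)
  sim <- renderAssay(cfg, nuclei = FALSE)
  lay <- sim@layout
  loci <- detectWells(sim@stacks$ref[, , 1], lay)

  # static stack: all translations are zero
  tk <- trackArray(loci, sim@stacks$ref, lay)
  expect_equal(tk$dx[1], 0)
  expect_lt(max(abs(tk$dx)), 0.5)
  expect_lt(max(abs(tk$dy)), 0.5)

  # inject a uniform 3-px x-shift from frame 4 on
  shifted <- sim@stacks$ref
  for (t in 4:6) {
    m <- shifted[, , t]
    shifted[, , t] <- cbind(m[, 1:3], m[, 1:(ncol(m) - 3)])
  }
  tk2 <- trackArray(loci, shifted, lay)
  expect_lt(max(abs(tk2$dx[1:3])), 0.5)
  expect_equal(tk2$dx[4:6], rep(3, 3), tolerance = 0.5)
  expect_lt(max(abs(tk2$dy)), 0.5)
})

test_that("the detection pipeline assigns correct grid indices on default
           study conditions", {
  fx <- fxDefaultAssay()
  tr <- groundTruth(fx$sim)
  loci <- fx$loci
  m <- fx$match
  nonDef <- which(!tr$defective)
  matched <- !is.na(m) & m %in% nonDef
  # every matched non-defective well carries the ground-truth grid index
  idxOk <- loci$row[matched] == tr$row[m[matched]] &
    loci$col[matched] == tr$col[m[matched]]
  recovered <- sum(idxOk) / length(nonDef)
  expect_gte(recovered, 0.99)
  expect_false(any(duplicated(paste(loci$row, loci$col))))
})
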