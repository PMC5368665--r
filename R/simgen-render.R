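# Renders complete synthetic assays: three-channel drawdown + purge image
# stacks, a high-magnification nuclei image set, and the ground-truth table.

# Channel base intensities (counts, before gain field and noise). The sensor
# film covers the whole lid, so the area outside wells responds to the
# ambient oxygen concentration; well lips image bright in every channel.
.REF_BG <- 0.8       # reference background, x baseCounts
.REF_INTERIOR <- 1.0
.LIP_GAIN <- 3.0     # lip brightness, x baseCounts
.DEFECT_INTERIOR <- 0.3  # sensor-void interior (bare glass), x baseCounts

# Smooth low-order polynomial gain field emulating sensor-film heterogeneity.
.gainField <- function(h, w, amp) {
  if (amp <= 0) return(matrix(1, h, w))
  xs <- seq(-1, 1, length.out = w)
  ys <- seq(-1, 1, length.out = h)
  cf <- rnorm(5, 0, amp)
  g <- 1 + cf[1] * outer(ys * 0 + 1, xs) + cf[2] * outer(ys, xs * 0 + 1) +
    cf[3] * outer(ys, xs) +
    cf[4] * outer(ys * 0 + 1, xs^2 - 0.5) + cf[5] * outer(ys^2 - 0.5, xs * 0 + 1)
  pmax(g, 0.2)
}

#' Render a complete synthetic microwell assay
#'
#' Composes the forward sensor models into multi-frame image stacks for the
#' oxygen, pH and reference channels, plus a high-magnification nuclei image
#' pair for cell counting, and returns them together with the hidden ground
#' truth. Wells are hexagonally packed bright-lipped circles; interiors
#' follow [forwardOxygenTrace()] / [forwardPhTrace()] scaled by a smooth
#' film-heterogeneity field; a configurable fraction of wells is unsealed
#' (relaxing toward ambient oxygen and responding to the terminal purge) or
#' rendered defective (broken lip, sensor void). Multiplicative noise,
#' additive read noise and rigid stage drift are applied per frame.
#' All sealed wells additionally carry the configured photo-consumption
#' drift, so empty sealed wells show the slight intensity rise
#' characteristic of oxygen consumption by the sensor itself.
#'
#' The entire simulation is deterministic given `cfg@rngSeed`; with
#' `noiseCv = 0`, `readNoise = 0` and no drift the rendered frames of empty
#' wells repeat pixel-exactly.
#'
#' @param cfg a [SimConfig-class].
#' @param cellCounts optional integer vector overriding random seeding (one
#'   entry per well, row-major; used to construct designed cohorts such as
#'   all-single-cell arrays).
#' @param sealed,defective optional logical vectors overriding the random
#'   leak / defect draws.
#' @param nuclei render the nuclei image set (set `FALSE` to save time when
#'   only the assay stacks are needed).
#' @param nucleiScale magnification ratio of the cell-count images relative
#'   to the assay images (objective change).
#' @return A [SimulatedAssay-class].
#' @examples
#' cfg <- simConfig(gridRows = 4, gridCols = 4, nFrames = 10, purgeFrames = 5,
#'                  noiseCv = 0, leakFraction = 0, defectFraction = 0)
#' sim <- renderAssay(cfg)
#' sim
#' @export
renderAssay <- function(cfg, cellCounts = NULL, sealed = NULL,
                        defective = NULL, nuclei = TRUE, nucleiScale = 2.5) {
  stopifnot(is(cfg, "SimConfig"))
  layout <- layoutFromConfig(cfg)
  pitch <- layout@pitchPx
  R <- layout@wellRadiusPx
  margin <- pitch
  centers <- .hexCenters(cfg@gridRows, cfg@gridCols, pitch, margin)
  nw <- nrow(centers)
  w <- as.integer(ceiling(max(centers$x) + margin))
  h <- as.integer(ceiling(max(centers$y) + margin))
  if (as.double(w) * h > 5e7)
    stop(sprintf("rendered image would be %d x %d pixels; reduce the grid or increase pixelSizeUm", h, w))
  nTotal <- as.double(w) * h * (cfg@nFrames + cfg@purgeFrames) * 3
  if (nTotal > 4e8)
    stop(sprintf(
      "rendered stacks would hold %.1e values (> 3 GB); reduce the grid, frame count or resolution",
      nTotal))

  set.seed(cfg@rngSeed)

  # --- ground truth ----------------------------------------------------------
  if (is.null(cellCounts))
    cellCounts <- .truncPois(nw, cfg@seedingMean, cfg@maxCellsPerWell)
  stopifnot(length(cellCounts) == nw)
  if (is.null(sealed)) sealed <- runif(nw) >= cfg@leakFraction
  if (is.null(defective)) defective <- runif(nw) < cfg@defectFraction
  mlOcr <- log(cfg@ocrMedian); slOcr <- log(cfg@ocrGsd)
  mlEcar <- log(cfg@ecarMedian); slEcar <- log(cfg@ecarGsd)
  trueOcr <- vapply(cellCounts, function(k)
    if (k == 0L) 0 else sum(rlnorm(k, mlOcr, slOcr)), numeric(1))
  trueEcar <- vapply(cellCounts, function(k)
    if (k == 0L) 0 else sum(rlnorm(k, mlEcar, slEcar)), numeric(1))

  truth <- data.frame(
    well = seq_len(nw) - 1L, row = centers$row, col = centers$col,
    x = centers$x, y = centers$y,
    cellCount = cellCounts, trueOcr = trueOcr, trueEcar = trueEcar,
    sealed = sealed, defective = defective
  )

  # --- per-well intensity traces --------------------------------------------
  times <- .frameTimes(cfg)
  nT <- length(times)
  purgeStart <- if (cfg@purgeFrames > 0L) cfg@nFrames + 1L else NA_integer_
  pOcr <- .photoOcr(cfg)
  o2I <- matrix(0, nw, nT)
  phI <- matrix(0, nw, nT)
  for (i in seq_len(nw)) {
    o2I[i, ] <- forwardOxygenTrace(trueOcr[i] + if (sealed[i]) pOcr else 0,
                                   cfg, sealed = sealed[i])$intensity
    phI[i, ] <- forwardPhTrace(trueEcar[i], cfg)$intensity
  }

  # --- static geometry -------------------------------------------------------
  interiorIdx <- vector("list", nw)
  lipIdx <- vector("list", nw)
  for (i in seq_len(nw)) {
    cx <- centers$x[i]; cy <- centers$y[i]
    interior <- .diskIndices(cx, cy, 0.88 * R, h, w)
    lip <- .annulusIndices(cx, cy, 0.88 * R, 1.15 * R, h, w)
    if (defective[i]) {
      # broken lip: remove a 120-degree arc
      ly <- ((lip - 1L) %% h)
      lx <- ((lip - 1L) %/% h)
      ang <- atan2(ly - cy, lx - cx)
      lip <- lip[!(ang > 0 & ang < 2 * pi / 3)]
    }
    interiorIdx[[i]] <- interior
    lipIdx[[i]] <- lip
  }

  gain <- .gainField(h, w, cfg@gainFieldAmp)
  k <- .kSvFromConfig(cfg)
  i0Film <- cfg@baseCounts * cfg@o2Ratio
  bg <- list(
    o2 = function(ambient) i0Film / (1 + k * ambient),
    ph = cfg@baseCounts,
    ref = cfg@baseCounts * .REF_BG
  )

  drift <- data.frame(frame = seq_len(nT),
                      dx = round((seq_len(nT) - 1) * cfg@driftPxPerFrame),
                      dy = 0)

  refInterior <- cfg@baseCounts * .REF_INTERIOR
  lipVal <- cfg@baseCounts * .LIP_GAIN
  defVal <- cfg@baseCounts * .DEFECT_INTERIOR

  stacks <- list()
  for (ch in c("o2", "ph", "ref")) {
    arr <- array(0, c(h, w, nT))
    for (t in seq_len(nT)) {
      ambient <- if (!is.na(purgeStart) && t >= purgeStart) cfg@purgeO2Um
                 else cfg@oAirUm
      canvas <- matrix(if (ch == "o2") bg$o2(ambient) else bg[[ch]], h, w)
      for (i in seq_len(nw)) {
        canvas[lipIdx[[i]]] <- lipVal
        canvas[interiorIdx[[i]]] <-
          if (defective[i]) defVal
          else if (ch == "o2") o2I[i, t]
          else if (ch == "ph") phI[i, t]
          else refInterior
      }
      canvas <- canvas * gain
      if (drift$dx[t] != 0 || drift$dy[t] != 0)
        canvas <- .shiftMatrix(canvas, drift$dx[t], drift$dy[t],
                               fill = mean(canvas))
      if (cfg@noiseCv > 0)
        canvas <- canvas * (1 + cfg@noiseCv * matrix(rnorm(h * w), h, w))
      if (cfg@readNoise > 0)
        canvas <- canvas + matrix(rnorm(h * w, 0, cfg@readNoise), h, w)
      arr[, , t] <- canvas
    }
    stacks[[ch]] <- arr
  }

  # --- nuclei image set (cell-count magnification) ---------------------------
  if (nuclei) {
    nh <- as.integer(ceiling(h * nucleiScale))
    nwd <- as.integer(ceiling(w * nucleiScale))
    nucBg <- 0.1 * cfg@baseCounts
    nucImg <- matrix(nucBg, nh, nwd)
    nucRef <- matrix(cfg@baseCounts * .REF_BG, nh, nwd)
    sigma <- 1.6                      # nucleus blob scale, px at 10X (~10 um)
    kk <- as.integer(ceiling(3 * sigma))
    ax <- (-kk):kk
    blob <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
    for (i in seq_len(nw)) {
      cx <- centers$x[i] * nucleiScale; cy <- centers$y[i] * nucleiScale
      lip <- .annulusIndices(cx, cy, 0.88 * R * nucleiScale,
                             1.15 * R * nucleiScale, nh, nwd)
      nucRef[lip] <- cfg@baseCounts * .LIP_GAIN
      nucImg[lip] <- 0.25 * cfg@baseCounts   # faint well-associated artifact
      kcells <- cellCounts[i]
      if (kcells > 0L) {
        pos <- .scatterInDisk(kcells, cx, cy, 0.8 * R * nucleiScale,
                              minSep = 3.5 * sigma)
        for (j in seq_len(kcells)) {
          px <- as.integer(round(pos$x[j])); py <- as.integer(round(pos$y[j]))
          ys <- (py - kk):(py + kk) + 1L
          xs <- (px - kk):(px + kk) + 1L
          ok <- ys >= 1L & ys <= nh
          okx <- xs >= 1L & xs <= nwd
          nucImg[ys[ok], xs[okx]] <- nucImg[ys[ok], xs[okx]] +
            cfg@baseCounts * blob[ok, okx]
        }
      }
    }
    if (cfg@noiseCv > 0) {
      nucImg <- nucImg * (1 + cfg@noiseCv * matrix(rnorm(nh * nwd), nh, nwd))
      nucRef <- nucRef * (1 + cfg@noiseCv * matrix(rnorm(nh * nwd), nh, nwd))
    }
  } else {
    nucImg <- matrix(0, 0, 0)
    nucRef <- matrix(0, 0, 0)
  }

  new("SimulatedAssay", stacks = stacks, nuclei = nucImg, nucleiRef = nucRef,
      truth = truth, times = times, purgeStart = purgeStart,
      drift = drift, nucleiScale = nucleiScale, config = cfg, layout = layout)
}

# Rejection-sample k points inside a disk with pairwise separation >= minSep
# (relaxes the separation if the disk is too crowded).
.scatterInDisk <- function(k, cx, cy, r, minSep) {
  xs <- numeric(k); ys <- numeric(k)
  sep <- minSep
  placed <- 0L
  tries <- 0L
  while (placed < k) {
    a <- runif(1, 0, 2 * pi)
    d <- r * sqrt(runif(1))
    x <- cx + d * cos(a); y <- cy + d * sin(a)
    if (placed == 0L ||
        all((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2 >= sep^2)) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
    tries <- tries + 1L
    if (tries %% 200L == 0L) sep <- sep * 0.8  # crowded well: relax
  }
  list(x = xs, y = ys)
}

#' Write / read a simulated assay to plain files
#'
#' `writeAssay()` stores each channel as a multi-page 16-bit TIFF (one page
#' per timepoint), the nuclei image pair as TIFFs, the ground truth as CSV,
#' and timestamps plus configuration as a JSON sidecar. `readAssay()`
#' reconstructs the stacks and metadata.
#'
#' @param sim a [SimulatedAssay-class].
#' @param dir output directory (created if missing).
#' @return `writeAssay()` returns `dir` invisibly; `readAssay()` a list with
#'   elements `stacks`, `nuclei`, `nucleiRef`, `truth`, `times`,
#'   `purgeStart`.
#' @export
writeAssay <- function(sim, dir) {
  stopifnot(is(sim, "SimulatedAssay"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  top <- max(unlist(lapply(sim@stacks, max)), sim@nuclei, sim@nucleiRef, 1)
  for (ch in names(sim@stacks)) {
    pages <- lapply(seq_len(dim(sim@stacks[[ch]])[3]), function(t)
      pmin(pmax(sim@stacks[[ch]][, , t] / top, 0), 1))
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16)
  }
  if (length(sim@nuclei) > 0) {
    tiff::writeTIFF(pmin(pmax(sim@nuclei / top, 0), 1),
                    file.path(dir, "nuclei.tif"), bits.per.sample = 16)
    tiff::writeTIFF(pmin(pmax(sim@nucleiRef / top, 0), 1),
                    file.path(dir, "nuclei_ref.tif"), bits.per.sample = 16)
  }
  write.csv(sim@truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(times = sim@times, purgeStart = sim@purgeStart,
         intensityScale = top, nucleiScale = sim@nucleiScale,
         drift = sim@drift),
    file.path(dir, "assay.json"), auto_unbox = TRUE, digits = NA)
  writeSimConfig(sim@config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname writeAssay
#' @export
readAssay <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "assay.json"),
                              simplifyVector = TRUE)
  top <- meta$intensityScale
  stacks <- lapply(c(o2 = "o2", ph = "ph", ref = "ref"), function(ch) {
    pages <- tiff::readTIFF(file.path(dir, paste0(ch, ".tif")), all = TRUE)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * top
    arr
  })
  nucPath <- file.path(dir, "nuclei.tif")
  nuclei <- if (file.exists(nucPath)) tiff::readTIFF(nucPath) * top else NULL
  nucRefPath <- file.path(dir, "nuclei_ref.tif")
  nucleiRef <- if (file.exists(nucRefPath)) tiff::readTIFF(nucRefPath) * top else NULL
  list(stacks = stacks, nuclei = nuclei, nucleiRef = nucleiRef,
       truth = read.csv(file.path(dir, "ground_truth.csv")),
       times = meta$times,
       purgeStart = if (is.null(meta$purgeStart)) NA_integer_ else meta$purgeStart)
}
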