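# End-to-end assay analysis: detection -> extraction -> QC -> seal ->
# calibration -> rates -> per-cell normalization.

#' Match detected wells to ground-truth wells by position
#'
#' @param loci detected well table (`x`, `y`).
#' @param truth ground-truth table from [groundTruth()].
#' @param tolerance maximum center distance, pixels.
#' @return Integer vector: for each locus the matching truth row index, or
#'   `NA` when no truth well lies within tolerance.
#' @export
matchWellsToTruth <- function(loci, truth, tolerance) {
  vapply(seq_len(nrow(loci)), function(i) {
    d2 <- (truth$x - loci$x[i])^2 + (truth$y - loci$y[i])^2
    j <- which.min(d2)
    if (d2[j] <= tolerance^2) j else NA_integer_
  }, integer(1))
}

#' Analyse a microwell assay end-to-end
#'
#' Runs the full pipeline on a simulated (or loaded) assay: well detection
#' on the first reference frame, optional rigid tracking, region-trace
#' extraction, ratiometric normalization, CV-based well QC, seal
#' classification from the purge phase, local Stern-Volmer calibration,
#' linear-window OCR/ECAR regression, nuclei counting (via the 4X to 10X
#' similarity registration) and per-cell normalization. Leaky and QC-fail
#' wells are excluded from the rate tables but their records are retained
#' with their status.
#'
#' @param sim a [SimulatedAssay-class] (or a list with the same fields, as
#'   returned by [readAssay()] plus `config`/`layout`).
#' @param phCal a [PHCalibration-class]; `NULL` fits one from a simulated
#'   buffer-titration series of the configured sensor (pH 3-9, 25 points).
#' @param counts optional data.frame (`row`, `col`, `count`) supplying cell
#'   counts externally; by default counts come from the nuclei images.
#' @param track run rigid tracking over the reference stack.
#' @param qcCutoff CV cutoff (percent) for [inspectWells()]; `NULL` = robust
#'   default.
#' @param alpha significance level for seal and response calls.
#' @param backgroundSubtract subtract the empty-well background OCR from
#'   occupied wells (off by default; the background is reported either way).
#' @return list with `records` (one row per detected well), `loci`, `qc`,
#'   `seal`, `o2cal`, `phCal`, `traces`, `background`, `transform10x`.
#' @export
analyzeAssay <- function(sim, phCal = NULL, counts = NULL, track = FALSE,
                         qcCutoff = NULL, alpha = 0.01,
                         backgroundSubtract = FALSE) {
  stopifnot(is(sim, "SimulatedAssay"))
  cfg <- sim@config
  layout <- sim@layout
  refFrame <- sim@stacks$ref[, , 1]

  loci <- detectWells(refFrame, layout)
  # region geometry follows the layout radius; the Hough radius estimate is
  # only accurate to the 1-px accumulator resolution
  r <- layout@wellRadiusPx

  rigid <- NULL
  if (isTRUE(track))
    rigid <- trackArray(loci, sim@stacks$ref, layout)

  spec <- regionSpec(r)
  traces <- extractRegionTraces(sim@stacks[c("o2", "ph", "ref")], loci, spec,
                                sim@times, track = rigid,
                                purgeStart = sim@purgeStart)
  traces <- normalizeRatiometric(traces)

  segs <- segmentWells(refFrame, loci, halfSize = as.integer(floor(1.3 * r)))
  refWell <- buildReferenceWell(segs)
  qc <- inspectWells(segs, refWell, cutoff = qcCutoff)

  o2c <- traceMatrix(traces, "o2", "center")
  phc <- traceMatrix(traces, "ph", "center")
  nT <- length(sim@times)
  drawdownEnd <- if (!is.na(sim@purgeStart)) sim@purgeStart - 1L else nT

  seal <- NULL
  sealedVec <- rep(TRUE, nrow(loci))
  if (!is.na(sim@purgeStart) && nT - sim@purgeStart + 1L >= 5L) {
    outsideTrace <- colMeans(traces@means[, "o2", "outside", , drop = TRUE],
                             na.rm = TRUE)
    seal <- classifySeal(o2c, sim@times, sim@purgeStart,
                         outsideTrace = outsideTrace, alpha = alpha)
    sealedVec <- !is.na(seal$sealed) & seal$sealed
  }

  eligible <- qc$status == "pass" & sealedVec & traces@wells$inBounds
  o2cal <- localO2Calibration(o2c, sim@times, drawdownEnd = drawdownEnd,
                              oAirUm = cfg@oAirUm, eligible = eligible)

  if (is.null(phCal)) {
    calSeries <- makeCalibrationSeries(cfg@phParams,
                                       seq(3, 9, length.out = 25),
                                       mediumPh = cfg@phStart)
    phCal <- fitPhSigmoid(calSeries$ph, calSeries$intensity,
                          mediumPh = cfg@phStart)
  }

  nw <- nrow(loci)
  ocr <- ocrSe <- ocrCi <- ocrR2 <- rep(NA_real_, nw)
  ecar <- ecarSe <- ecarCi <- rep(NA_real_, nw)
  plateau <- rep(NA, nw)
  tt <- sim@times[seq_len(drawdownEnd)]
  for (i in seq_len(nw)) {
    yI <- o2c[i, seq_len(drawdownEnd)]
    if (any(is.na(yI)) || o2cal$perWell$kSv[i] <= 0) next
    o2 <- (o2cal$perWell$i0[i] / yI - 1) / o2cal$perWell$kSv[i]
    o2 <- pmax(o2, 0)
    lw <- tryCatch(findLinearWindow(o2, tt,
                                    plateauValueMax = 0.1 * cfg@oAirUm),
                   error = function(e) NULL)
    if (is.null(lw)) next
    est <- tryCatch(computeOcr(o2, tt, layout@wellVolumePl, lw$window),
                    error = function(e) NULL)
    if (is.null(est)) next
    ocr[i] <- est$ocr; ocrSe[i] <- est$se; ocrCi[i] <- est$ciPercent
    ocrR2[i] <- est$r2; plateau[i] <- lw$plateauReached

    yP <- phc[i, seq_len(drawdownEnd)]
    if (!any(is.na(yP)) && all(yP > 0)) {
      phSeries <- tryCatch(
        phTraceToPh(yP, phCal, mediumPh = cfg@phStart, tol = 0.1),
        error = function(e) NULL)
      if (!is.null(phSeries)) {
        lwP <- tryCatch(findLinearWindow(as.numeric(phSeries), tt),
                        error = function(e) NULL)
        if (!is.null(lwP)) {
          estP <- tryCatch(computeEcar(as.numeric(phSeries), tt, lwP$window),
                           error = function(e) NULL)
          if (!is.null(estP)) {
            ecar[i] <- estP$ecar; ecarSe[i] <- estP$se
            ecarCi[i] <- estP$ciPercent
          }
        }
      }
    }
  }

  # ---- cell counts ----------------------------------------------------------
  tf10 <- NULL
  cellCount <- rep(NA_integer_, nw)
  if (!is.null(counts)) {
    m <- merge(data.frame(idx = seq_len(nw), row = loci$row, col = loci$col),
               counts, by = c("row", "col"), all.x = TRUE)
    cellCount[m$idx] <- m$count
  } else if (length(sim@nuclei) > 0) {
    layout10 <- arrayLayout(layout@gridRows, layout@gridCols,
                            layout@wellRadiusPx * sim@nucleiScale,
                            layout@pitchPx * sim@nucleiScale,
                            layout@wellVolumePl)
    loci10 <- detectWells(sim@nucleiRef, layout10)
    corr <- merge(loci[, c("row", "col", "x", "y")],
                  loci10[, c("row", "col", "x", "y")],
                  by = c("row", "col"), suffixes = c("A", "B"))
    if (nrow(corr) >= 2L) {
      tf10 <- fitSimilarityTransform(cbind(corr$xA, corr$yA),
                                     cbind(corr$xB, corr$yB))
      pts10 <- applyTransform(tf10, loci)
      wells10 <- data.frame(wellId = loci$wellId,
                            x = pts10[, 1], y = pts10[, 2])
      cc <- countWellNuclei(sim@nuclei, wells10,
                            halfSize = as.integer(floor(1.3 * r *
                                                          sim@nucleiScale)))
      cellCount <- cc$count
    }
  }

  # ---- background, response class, per-cell rates ---------------------------
  retained <- eligible
  emptyIdx <- which(retained & !is.na(cellCount) & cellCount == 0L &
                      is.finite(ocr))
  background <- tryCatch(estimateBackgroundOcr(ocr[emptyIdx]),
                         error = function(e) NULL)
  bg <- if (!is.null(background)) background$background else 0
  if (backgroundSubtract && !is.null(background))
    ocr[retained & !is.na(cellCount) & cellCount > 0L] <-
      ocr[retained & !is.na(cellCount) & cellCount > 0L] - bg

  response <- vapply(seq_len(nw), function(i) {
    classifyResponse(cellCount[i], ocr[i], ocrSe[i], ecar[i], ecarSe[i],
                     backgroundOcr = bg, alpha = alpha)
  }, character(1))

  records <- data.frame(
    wellId = loci$wellId, row = loci$row, col = loci$col,
    x = loci$x, y = loci$y,
    cvPercent = qc$cvPercent, qcStatus = qc$status,
    sealed = sealedVec, inBounds = traces@wells$inBounds,
    retained = retained,
    cellCount = cellCount, responseClass = response,
    ocr = ocr, ocrSe = ocrSe, ocrCiPercent = ocrCi, ocrR2 = ocrR2,
    plateauReached = plateau,
    ecar = ecar, ecarSe = ecarSe, ecarCiPercent = ecarCi
  )
  records <- normalizePerCell(records)
  records$perCellOcr[!retained] <- NA_real_
  records$perCellEcar[!retained] <- NA_real_

  list(records = records, loci = loci, qc = qc, seal = seal,
       o2cal = o2cal, phCal = phCal, traces = traces,
       background = background, transform10x = tf10)
}

#' Normalize condition rates to basal rates
#'
#' For comparisons of perturbagen responses against basal respiration
#' (mirroring bulk-instrument practice where absolute cell numbers are
#' uncertain): the ratio of condition median to basal median.
#'
#' @param conditionRates,basalRates numeric rate samples.
#' @return Median ratio (dimensionless).
#' @export
normalizeToBasal <- function(conditionRates, basalRates) {
  b <- median(basalRates[is.finite(basalRates)])
  if (!is.finite(b) || b == 0) stop("degenerate basal sample")
  median(conditionRates[is.finite(conditionRates)]) / b
}
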