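# Rate estimation and population statistics: linear-window finding, OCR and
# ECAR from regression slopes, empty-well background, response
# classification, per-cell normalization, KS population comparison and
# occupancy analysis.

#' Find the early linear window of a drawdown trace
#'
#' Two-phase breakpoint scan: for every candidate window end `k` the series
#' is modelled as one line over frames `1..k` plus a second line over the
#' remainder, and the pooled residual variance is minimized; among
#' statistically tied candidates the longest early window wins, so an
#' unbroken linear series keeps its full window. The series has reached a
#' plateau when the segment after the window is flat (within noise) and the
#' series changed by substantially more than noise overall. Sign-agnostic,
#' so it serves both the falling oxygen-concentration traces and the rising
#' reciprocal-intensity traces used for local calibration.
#'
#' @param series numeric trace (>= 6 frames).
#' @param times timestamps, minutes, strictly increasing.
#' @param minWindow smallest admissible window length, frames.
#' @param noiseScale per-frame noise SD used by the plateau test; `NULL`
#'   estimates it robustly from second differences (which vanish on linear
#'   segments).
#' @param tieMult candidates whose pooled residual variance is within this
#'   factor of the minimum count as ties.
#' @param plateauValueMax optional absolute ceiling the post-window mean must
#'   stay under for `plateauReached` (e.g. a near-zero oxygen concentration).
#' @return list(`window` = c(start, end) frame indices, `plateauReached`,
#'   `slope`, `rmse`, `noiseScale`).
#' @export
findLinearWindow <- function(series, times, minWindow = 4L,
                             noiseScale = NULL, tieMult = 1.25,
                             plateauValueMax = NULL) {
  n <- length(series)
  if (n < 6L) stop("need at least 6 frames to find a linear window")
  stopifnot(length(times) == n, all(diff(times) > 0))
  if (minWindow < 4L) minWindow <- 4L
  if (is.null(noiseScale)) {
    noiseScale <- mad(diff(series, differences = 2)) / sqrt(6)
  }
  eps <- 1e-9 * max(abs(series), 1)

  rss <- function(ix) {
    f <- stats::.lm.fit(cbind(1, times[ix]), series[ix])
    sum(f$residuals^2)
  }
  score <- rep(Inf, n)
  for (k in minWindow:n) {
    r1 <- rss(1:k)
    if (k <= n - 3L) { r2 <- rss((k + 1L):n); df <- n - 4L }
    else { r2 <- 0; df <- n - 2L }
    score[k] <- (r1 + r2) / df
  }
  mn <- min(score[minWindow:n])
  kBest <- max(which(score <= mn * tieMult + eps^2))
  fitBest <- .olsLine(times[1:kBest], series[1:kBest])

  plateau <- FALSE
  if (kBest <= n - 3L) {
    post <- series[(kBest + 1L):n]
    tPost <- times[(kBest + 1L):n]
    pfit <- .olsLine(tPost, post)
    sxx <- sum((tPost - mean(tPost))^2)
    seFloor <- max(noiseScale, eps) / sqrt(sxx)
    flat <- abs(pfit$slope) < 3 * seFloor
    moved <- abs(mean(post) - series[1]) > 5 * max(noiseScale, eps)
    valueOk <- is.null(plateauValueMax) || mean(post) <= plateauValueMax
    plateau <- flat && moved && valueOk
  }
  list(window = c(1L, kBest), plateauReached = plateau,
       slope = fitBest$slope, rmse = fitBest$rmse, noiseScale = noiseScale)
}

#' Oxygen consumption rate from a concentration trace
#'
#' OCR is the negative regression slope of dissolved oxygen against time
#' over the linear window, scaled by the well volume:
#' `OCR (fmol/min) = -slope (uM/min) * V (pL) / 1000`. The 95% confidence
#' interval comes from the ordinary least-squares slope standard error.
#'
#' @param o2Um dissolved-oxygen trace, uM.
#' @param times timestamps, minutes.
#' @param volumePl well volume, pL.
#' @param window `c(start, end)` frame indices (from [findLinearWindow()]).
#' @return list(`ocr` fmol/min, `se`, `ciPercent` relative 95% half-width,
#'   `r2`, `window`).
#' @examples
#' t <- 0:16
#' o2 <- pmax(0, 200 - 12.4031 * t)    # full drawdown in ~16.1 min
#' compute <- computeOcr(o2, t, 64.5, c(1, 16))
#' round(compute$ocr, 2)               # 0.80 fmol/min
#' @export
computeOcr <- function(o2Um, times, volumePl, window) {
  stopifnot(volumePl > 0, length(window) == 2L,
            window[2] > window[1] + 2)
  idx <- window[1]:window[2]
  y <- o2Um[idx]; tt <- times[idx]
  if (any(!is.finite(y)) || any(!is.finite(tt)))
    stop("non-finite values inside the regression window")
  fit <- .olsLine(tt, y)
  ocr <- -fit$slope * volumePl / 1000
  se <- fit$se * volumePl / 1000
  hw <- qt(0.975, fit$df) * se
  list(ocr = ocr, se = se,
       ciPercent = if (ocr != 0) 100 * hw / abs(ocr) else Inf,
       r2 = fit$r2, window = window)
}

#' Extracellular acidification rate from a pH trace
#'
#' ECAR is the negative regression slope of pH against time over the linear
#' window (positive = acidification), in pH/min.
#'
#' @param ph pH trace.
#' @param times timestamps, minutes.
#' @param window `c(start, end)` frame indices.
#' @return list(`ecar` pH/min, `se`, `ciPercent`, `r2`, `window`).
#' @export
computeEcar <- function(ph, times, window) {
  stopifnot(length(window) == 2L, window[2] > window[1] + 2)
  idx <- window[1]:window[2]
  y <- ph[idx]; tt <- times[idx]
  if (any(!is.finite(y)) || any(!is.finite(tt)))
    stop("non-finite values inside the regression window")
  fit <- .olsLine(tt, y)
  ecar <- -fit$slope
  hw <- qt(0.975, fit$df) * fit$se
  list(ecar = ecar, se = fit$se,
       ciPercent = if (ecar != 0) 100 * hw / abs(ecar) else Inf,
       r2 = fit$r2, window = window)
}

#' Effective background OCR of empty wells
#'
#' Empty wells are negative controls; the oxygen sensor's own
#' photo-consumption gives them a small positive effective OCR, which bounds
#' the error on occupied-well OCR. Reports the median (with a MAD-based
#' spread) over empty sealed wells; subtraction from occupied wells is
#' opt-in downstream.
#'
#' @param emptyOcr numeric vector of effective OCR estimates from empty
#'   sealed QC-pass wells (>= 5 required).
#' @return list(`background` fmol/min, `mad`, `n`).
#' @export
estimateBackgroundOcr <- function(emptyOcr) {
  emptyOcr <- emptyOcr[is.finite(emptyOcr)]
  if (length(emptyOcr) < 5L)
    stop("background unavailable: need at least 5 empty sealed wells")
  list(background = median(emptyOcr), mad = mad(emptyOcr),
       n = length(emptyOcr))
}

#' Classify a well's metabolic response
#'
#' `empty` when the well holds no cells; `responding` when OCR or ECAR
#' significantly exceeds the background at level `alpha` (one-sided z-test
#' on the slope estimate); otherwise `non_responding`.
#'
#' @param cellCount cells in the well.
#' @param ocr,ocrSe,ecar,ecarSe rate estimates and their standard errors.
#' @param backgroundOcr,backgroundEcar background levels (default 0).
#' @param alpha significance level.
#' @return One of `"empty"`, `"responding"`, `"non_responding"`.
#' @export
classifyResponse <- function(cellCount, ocr, ocrSe, ecar, ecarSe,
                             backgroundOcr = 0, backgroundEcar = 0,
                             alpha = 0.01) {
  if (!is.na(cellCount) && cellCount == 0) return("empty")
  z <- qnorm(1 - alpha)
  ocrSig <- is.finite(ocr) && is.finite(ocrSe) && ocrSe > 0 &&
    (ocr - backgroundOcr) / ocrSe > z
  ecarSig <- is.finite(ecar) && is.finite(ecarSe) && ecarSe > 0 &&
    (ecar - backgroundEcar) / ecarSe > z
  if (ocrSig || ecarSig) "responding" else "non_responding"
}

#' Normalize well rates to per-cell rates
#'
#' Per-cell rate = well rate / cell count; single-cell wells are flagged for
#' the single-cell analysis subset. Rows labelled occupied with a zero cell
#' count are an error; leaky and QC-fail wells must be excluded upstream.
#'
#' @param records data.frame with `cellCount`, `ocr`, `ecar` columns.
#' @return `records` with `perCellOcr`, `perCellEcar`, `singleCell` added
#'   (NA for empty wells).
#' @export
normalizePerCell <- function(records) {
  stopifnot(all(c("cellCount", "ocr", "ecar") %in% names(records)))
  if (!is.null(records$occupied) &&
      any(records$occupied & records$cellCount == 0, na.rm = TRUE))
    stop("occupied-labelled record with zero cell count")
  occ <- records$cellCount >= 1L
  records$perCellOcr <- ifelse(occ, records$ocr / records$cellCount, NA_real_)
  records$perCellEcar <- ifelse(occ, records$ecar / records$cellCount, NA_real_)
  records$singleCell <- records$cellCount == 1L
  records
}

#' Compare two rate populations
#'
#' Two-sample Kolmogorov-Smirnov test (exact for small samples, asymptotic
#' otherwise), medians, fold change of medians and per-sample coefficient of
#' variation.
#'
#' @param ratesA,ratesB numeric samples (ideally n >= 10 each).
#' @return list(`ksStatistic`, `pValue`, `medianA`, `medianB`,
#'   `foldChange` = medianB / medianA, `cvA`, `cvB`, `nA`, `nB`).
#' @export
comparePopulations <- function(ratesA, ratesB) {
  ratesA <- ratesA[is.finite(ratesA)]
  ratesB <- ratesB[is.finite(ratesB)]
  if (length(ratesA) == 0L || length(ratesB) == 0L)
    stop("empty sample in population comparison")
  exact <- min(length(ratesA), length(ratesB)) <= 25
  ks <- suppressWarnings(ks.test(ratesA, ratesB, exact = exact))
  mA <- median(ratesA); mB <- median(ratesB)
  list(ksStatistic = unname(ks$statistic), pValue = ks$p.value,
       medianA = mA, medianB = mB,
       foldChange = if (mA > 0) mB / mA else NA_real_,
       cvA = sd(ratesA) / mean(ratesA), cvB = sd(ratesB) / mean(ratesB),
       nA = length(ratesA), nB = length(ratesB))
}

#' Per-cell rates as a function of well occupancy
#'
#' Groups per-cell rates by cells per well, summarizes each group (median,
#' IQR, CV, OCR/ECAR ratio of medians), runs pairwise KS tests between
#' adjacent occupancy groups and a rank-correlation trend test of per-cell
#' rate against occupancy. With a single group the tests are skipped.
#'
#' @param records data.frame with `cellCount`, `perCellOcr`, `perCellEcar`.
#' @param occupancies occupancy levels to analyse.
#' @param minGroup smallest group size retained.
#' @return list(`groups` data.frame, `adjacentKs` data.frame or NULL,
#'   `ocrTrend`, `ecarTrend` (Spearman tests) or NULL).
#' @export
occupancyAnalysis <- function(records, occupancies = 1:5, minGroup = 10L) {
  stopifnot(all(c("cellCount", "perCellOcr", "perCellEcar") %in%
                  names(records)))
  recs <- records[records$cellCount %in% occupancies &
                    is.finite(records$perCellOcr), , drop = FALSE]
  keep <- names(which(table(recs$cellCount) >= minGroup))
  recs <- recs[recs$cellCount %in% as.integer(keep), , drop = FALSE]
  if (nrow(recs) == 0L) stop("no occupancy groups with enough wells")
  occs <- sort(unique(recs$cellCount))
  groups <- do.call(rbind, lapply(occs, function(k) {
    g <- recs[recs$cellCount == k, ]
    data.frame(
      cellsPerWell = k, n = nrow(g),
      medianPerCellOcr = median(g$perCellOcr),
      medianPerCellEcar = median(g$perCellEcar),
      iqrPerCellOcr = stats::IQR(g$perCellOcr),
      iqrPerCellEcar = stats::IQR(g$perCellEcar),
      cvPerCellOcr = sd(g$perCellOcr) / mean(g$perCellOcr),
      ocrEcarRatio = median(g$perCellOcr) / median(g$perCellEcar)
    )
  }))
  if (length(occs) < 2L)
    return(list(groups = groups, adjacentKs = NULL, ocrTrend = NULL,
                ecarTrend = NULL))
  adjacent <- do.call(rbind, lapply(seq_len(length(occs) - 1L), function(j) {
    a <- recs$perCellOcr[recs$cellCount == occs[j]]
    b <- recs$perCellOcr[recs$cellCount == occs[j + 1L]]
    ks <- suppressWarnings(ks.test(a, b))
    aE <- recs$perCellEcar[recs$cellCount == occs[j]]
    bE <- recs$perCellEcar[recs$cellCount == occs[j + 1L]]
    ksE <- suppressWarnings(ks.test(aE, bE))
    data.frame(occA = occs[j], occB = occs[j + 1L],
               ksOcr = unname(ks$statistic), pOcr = ks$p.value,
               ksEcar = unname(ksE$statistic), pEcar = ksE$p.value)
  }))
  ocrTrend <- suppressWarnings(
    cor.test(recs$cellCount, recs$perCellOcr, method = "spearman"))
  ecarTrend <- suppressWarnings(
    cor.test(recs$cellCount, recs$perCellEcar, method = "spearman"))
  list(groups = groups, adjacentKs = adjacent, ocrTrend = ocrTrend,
       ecarTrend = ecarTrend)
}
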