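# Sensor physics: Stern-Volmer oxygen calibration (two-point, local
# well-by-well, assay average) and the sigmoid pH sensor model with its
# closed-form inverse.

#' The sigmoid pH sensor model
#'
#' `I(pH) = i2 + (i1 - i2) / (1 + 10^(theta * (pKa - pH)))`: intensity rises
#' with pH between the dynamic-range limits `i2` and `i1`, with midpoint at
#' `pKa` and steepness `theta`.
#'
#' @param ph pH value(s).
#' @param params named numeric (or [PHCalibration-class]) with `i1`, `i2`,
#'   `pKa`, `theta`.
#' @return Intensity value(s).
#' @export
phSigmoid <- function(ph, params) {
  if (is(params, "PHCalibration"))
    params <- c(i1 = params@i1, i2 = params@i2, pKa = params@pKa,
                theta = params@theta)
  params[["i2"]] + (params[["i1"]] - params[["i2"]]) /
    (1 + 10^(params[["theta"]] * (params[["pKa"]] - ph)))
}

#' Two-point Stern-Volmer oxygen calibration
#'
#' From the intensities at air saturation and at zero oxygen:
#' `kSv = (I0 / I_air - 1) / [O_air]`. With two points the Stern-Volmer
#' regression is exact.
#'
#' @param iAir emission intensity in air-saturated medium.
#' @param i0 emission intensity at zero oxygen (must be >= `iAir`:
#'   quenching reduces intensity).
#' @param oAirUm dissolved oxygen at air saturation, uM (default 200, an
#'   air-saturated aqueous medium near 36-37 C at ~20 kPa pO2).
#' @return An [O2Calibration-class] with `source = "two_point"`.
#' @examples
#' fitO2TwoPoint(iAir = 1000, i0 = 2700, oAirUm = 200)  # kSv = 0.0085
#' @export
fitO2TwoPoint <- function(iAir, i0, oAirUm = 200) {
  if (!(i0 >= iAir && iAir > 0))
    stop("need I0 >= I_air > 0: dynamic quenching must reduce intensity")
  new("O2Calibration", kSv = (i0 / iAir - 1) / oAirUm, i0 = i0,
      oAirUm = oAirUm, source = "two_point")
}

#' Local well-by-well oxygen calibration from assay results
#'
#' Infers a two-point calibration per well from the assay itself: the
#' intensity at sealing (frame 0) is the air-saturated point and the
#' plateau intensity after full drawdown is the zero-oxygen point. The
#' Stern-Volmer constant is averaged over all wells that completed the
#' assay and the average is applied to every well - including wells that
#' did not draw down completely, such as empty wells - anchored at their
#' frame-0 intensity.
#'
#' @param o2Center matrix `[wells, frames]` of oxygen-channel center means
#'   (ratiometrically normalized if available).
#' @param times frame timestamps, minutes.
#' @param drawdownEnd last frame of the drawdown phase (frames after it,
#'   e.g. the purge, are ignored); default all frames.
#' @param oAirUm dissolved oxygen at air saturation, uM.
#' @param eligible logical vector marking wells allowed to contribute to the
#'   average (e.g. sealed, QC-pass); default all.
#' @return list with `perWell` (data.frame: `wellId`, `kSv`, `i0`,
#'   `completed`) and `average` (an [O2Calibration-class],
#'   `source = "assay_average"`).
#' @export
localO2Calibration <- function(o2Center, times, drawdownEnd = NULL,
                               oAirUm = 200, eligible = NULL) {
  if (is.null(dim(o2Center))) o2Center <- matrix(o2Center, nrow = 1)
  nw <- nrow(o2Center)
  if (is.null(drawdownEnd)) drawdownEnd <- ncol(o2Center)
  if (is.null(eligible)) eligible <- rep(TRUE, nw)
  tt <- times[seq_len(drawdownEnd)]
  kSv <- rep(NA_real_, nw)
  i0 <- rep(NA_real_, nw)
  completed <- rep(FALSE, nw)
  for (i in seq_len(nw)) {
    y <- o2Center[i, seq_len(drawdownEnd)]
    if (any(is.na(y)) || any(y <= 0)) next
    # the reciprocal intensity 1/I = (1 + kSv [O2]) / I0 is linear in [O2],
    # hence linear in time for a sealed well, with a plateau at 1/I0 once
    # the oxygen is exhausted: the linear-window finder applies directly
    lw <- findLinearWindow(1 / y, tt)
    if (lw$plateauReached && y[drawdownEnd] > y[1]) {
      iAir <- y[1]
      plateau <- mean(y[(lw$window[2] + 1L):drawdownEnd])
      if (plateau > iAir) {
        completed[i] <- TRUE
        kSv[i] <- (plateau / iAir - 1) / oAirUm
        i0[i] <- plateau
      }
    }
  }
  contrib <- completed & eligible
  if (!any(contrib))
    stop("no wells completed the assay: local calibration impossible, supply an external two-point calibration")
  kAvg <- mean(kSv[contrib])
  # non-completing wells: assay-average kSv anchored at the initial intensity
  fill <- !completed
  i0[fill] <- o2Center[fill, 1] * (1 + kAvg * oAirUm)
  kSv[fill] <- kAvg
  list(
    perWell = data.frame(wellId = seq_len(nw) - 1L, kSv = kSv, i0 = i0,
                         completed = completed),
    average = new("O2Calibration", kSv = kAvg,
                  i0 = mean(i0[contrib]), oAirUm = oAirUm,
                  source = "assay_average")
  )
}

#' Convert oxygen-sensor intensity to dissolved oxygen
#'
#' Inverts the Stern-Volmer law: `[O2] = (I0 / I - 1) / kSv`. Values that
#' invert to negative concentrations (intensity above `I0`, from noise at
#' the plateau) are clipped to zero and flagged.
#'
#' @param intensity positive intensity value(s).
#' @param cal an [O2Calibration-class] (or list with `kSv`, `i0`).
#' @return Numeric vector of concentrations, uM, with attribute `clipped`
#'   (logical vector).
#' @export
intensityToOxygen <- function(intensity, cal) {
  if (is.list(cal)) cal <- new("O2Calibration", kSv = cal$kSv, i0 = cal$i0,
                               oAirUm = if (!is.null(cal$oAirUm)) cal$oAirUm else 200,
                               source = "two_point")
  stopifnot(all(intensity > 0))
  if (cal@kSv == 0) stop("kSv = 0: the quenching law is not invertible")
  o2 <- (cal@i0 / intensity - 1) / cal@kSv
  clipped <- o2 < 0
  o2[clipped] <- 0
  attr(o2, "clipped") <- clipped
  o2
}

#' Fit the sigmoid pH sensor model to a calibration series
#'
#' Nonlinear least squares (multi-start Levenberg-Marquardt) of
#' `I(pH) = i2 + (i1 - i2) / (1 + 10^(theta * (pKa - pH)))`, after
#' normalizing the intensities to the assay-medium point. Starting values
#' come from the data range; additional jittered starts guard against local
#' minima.
#'
#' @param ph pH values (>= 5 distinct points spanning the transition).
#' @param intensity measured intensities (same length).
#' @param mediumPh the assay-medium pH used as normalization anchor; the raw
#'   intensity interpolated there is stored as `iRef`.
#' @param nStarts number of jittered multi-starts.
#' @return A [PHCalibration-class] with the fit RMS.
#' @export
fitPhSigmoid <- function(ph, intensity, mediumPh = 7.4, nStarts = 8) {
  stopifnot(length(ph) == length(intensity))
  if (length(unique(ph)) < 5L)
    stop("need at least 5 distinct pH points spanning the transition")
  ord <- order(ph)
  ph <- ph[ord]; intensity <- intensity[ord]
  iRefRaw <- if (mediumPh >= min(ph) && mediumPh <= max(ph))
    approx(ph, intensity, xout = mediumPh)$y else mean(intensity)
  y <- intensity / iRefRaw

  mkStart <- function(jit) {
    i1 <- max(y) * (1 + 0.05 * jit[1])
    i2 <- min(y) * (1 + 0.05 * jit[2])
    half <- (i1 + i2) / 2
    pKa <- ph[which.min(abs(y - half))] + 0.3 * jit[3]
    list(i1 = i1, i2 = i2, pKa = min(max(pKa, min(ph)), max(ph)),
         theta = exp(0.4 * jit[4]))
  }
  best <- NULL
  bestRss <- Inf
  # deterministic low-discrepancy jitter (leaves the user's RNG untouched)
  jseq <- sin(seq_len(4 * max(nStarts - 1, 0)) * 12.9898) * 1.5
  jits <- rbind(rep(0, 4),
                if (nStarts > 1) matrix(jseq, ncol = 4) else NULL)
  for (s in seq_len(nrow(jits))) {
    st <- mkStart(jits[s, ])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ i2 + (i1 - i2) / (1 + 10^(theta * (pKa - phv))),
        data = data.frame(phv = ph, y = y),
        start = st,
        lower = c(i1 = 0, i2 = 0, pKa = 0, theta = 1e-3),
        upper = c(i1 = 10 * max(y), i2 = max(y), pKa = 14, theta = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < bestRss) { bestRss <- rss; best <- fit }
  }
  if (is.null(best))
    stop("sigmoid fit failed to converge from all starts; check that the series spans the transition")
  cf <- coef(best)
  if (cf[["i1"]] <= cf[["i2"]])
    stop("sigmoid fit degenerate: fitted i1 <= i2")
  # renormalize to the fitted curve's own assay-medium value, which is exact
  # where the interpolated anchor used for conditioning is not
  atMedium <- phSigmoid(mediumPh, c(i1 = cf[["i1"]], i2 = cf[["i2"]],
                                    pKa = cf[["pKa"]], theta = cf[["theta"]]))
  new("PHCalibration", i1 = cf[["i1"]] / atMedium, i2 = cf[["i2"]] / atMedium,
      pKa = cf[["pKa"]], theta = cf[["theta"]], iRef = iRefRaw * atMedium,
      rms = sqrt(bestRss / length(y)))
}

#' Convert pH-sensor intensity to pH
#'
#' Closed-form inversion of the sigmoid model:
#' `pH = pKa - (1/theta) * log10((i1 - I) / (I - i2))`. Intensities must lie
#' strictly inside the dynamic range `(i2, i1)`; values outside it by less
#' than `tol` (relative to the dynamic range) are clamped to the edge and
#' flagged, values further out raise an error.
#'
#' @param intensity normalized intensity value(s).
#' @param cal a [PHCalibration-class].
#' @param tol clamping tolerance as a fraction of the dynamic range.
#' @return pH value(s) with attribute `clamped` (logical vector).
#' @export
intensityToPh <- function(intensity, cal, tol = 0.02) {
  stopifnot(is(cal, "PHCalibration"))
  rngW <- cal@i1 - cal@i2
  lo <- cal@i2 + 1e-6 * rngW
  hi <- cal@i1 - 1e-6 * rngW
  below <- intensity <= lo
  above <- intensity >= hi
  if (any(intensity < cal@i2 - tol * rngW | intensity > cal@i1 + tol * rngW,
          na.rm = TRUE))
    stop("intensity outside the sensor dynamic range beyond tolerance")
  x <- pmin(pmax(intensity, lo), hi)
  ph <- cal@pKa - (1 / cal@theta) * log10((cal@i1 - x) / (x - cal@i2))
  attr(ph, "clamped") <- below | above
  ph
}

#' Convert a raw pH-sensor intensity trace to pH
#'
#' Anchors the trace at the assay medium: the first frame is taken at
#' `mediumPh`, so the normalized trace is
#' `I(t) / I(0) * I_model(mediumPh)`, which [intensityToPh()] then inverts.
#'
#' @param trace raw intensity trace (frame 0 in assay medium).
#' @param cal a [PHCalibration-class].
#' @param mediumPh assay-medium pH.
#' @param tol passed to [intensityToPh()].
#' @return pH trace with the `clamped` attribute.
#' @export
phTraceToPh <- function(trace, cal, mediumPh = 7.4, tol = 0.02) {
  stopifnot(is(cal, "PHCalibration"))
  anchor <- phSigmoid(mediumPh, cal)
  intensityToPh(trace / trace[1] * anchor, cal, tol = tol)
}
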