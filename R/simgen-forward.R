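# Sensor-physics forward models: oxygen drawdown under the Stern-Volmer
# quenching law and pH decline under the sigmoid sensor model. These are the
# noise-free building blocks that renderAssay() composes into images.

# Frame timestamps (minutes) for a config: drawdown frames followed by the
# terminal purge frames. Frame 1 is t = 0.
.frameTimes <- function(cfg) {
  (seq_len(cfg@nFrames + cfg@purgeFrames) - 1) * cfg@frameIntervalMin
}

# Stern-Volmer constant implied by a config: kSv = (I0/I_air - 1) / [O_air].
.kSvFromConfig <- function(cfg) (cfg@o2Ratio - 1) / cfg@oAirUm

# Rate (uM/min) at which an OCR (fmol/min) lowers the dissolved oxygen
# concentration of a well of volume V (pL): fmol / pL = 1e-15 mol / 1e-12 L
# = 1e-3 mol/L, i.e. 1000 uM.
.ocrToUmPerMin <- function(ocr, volumePl) 1000 * ocr / volumePl

# Effective OCR (fmol/min) reproducing the configured photo-consumption
# drift: the oxygen level an empty sealed well must reach for its intensity
# to rise by `photoDrift` over the drawdown phase, converted to a constant
# consumption rate.
.photoOcr <- function(cfg) {
  if (cfg@photoDrift <= 0) return(0)
  k <- .kSvFromConfig(cfg)
  o2End <- ((1 + k * cfg@oAirUm) / (1 + cfg@photoDrift) - 1) / k
  tEnd <- max(cfg@nFrames - 1L, 1L) * cfg@frameIntervalMin
  (cfg@oAirUm - o2End) * cfg@wellVolumePl / 1000 / tEnd
}

#' Forward model of a single well's oxygen-sensor trace
#'
#' Simulates the dissolved-oxygen time course of one well and maps it to
#' sensor emission intensity through the Stern-Volmer law
#' `I = I0 / (1 + kSv * [O2])` with `kSv = (o2Ratio - 1) / [O_air]`.
#' Sealed wells draw down linearly, `[O2](t) = max(0, [O_air] - ocr * t / V)`
#' (the linear drawdown approximation), and hold their value during the
#' terminal purge. Unsealed wells exchange oxygen with the ambient medium at
#' a first-order rate, so they never deplete fully and during the purge they
#' relax toward the elevated purge concentration.
#'
#' @param trueOcr oxygen consumption rate, fmol/min (>= 0).
#' @param cfg a [SimConfig-class]; supplies volume, sensor ratio, frame
#'   timing and the purge phase.
#' @param sealed logical; is the well hermetically sealed?
#' @param times optional timestamps (minutes, strictly increasing) replacing
#'   the config's frame grid; when supplied, all frames are treated as
#'   drawdown frames unless `purgeStart` is given.
#' @param purgeStart 1-based index of the first purge frame; defaults to
#'   `cfg@nFrames + 1` on the config's frame grid.
#' @return A data.frame with columns `time` (min), `o2Um` (uM) and
#'   `intensity` (counts; air-saturated start equals `cfg@baseCounts`).
#' @examples
#' cfg <- simConfig(nFrames = 25, purgeFrames = 0)
#' tr <- forwardOxygenTrace(0.8, cfg)            # depletes at ~16.1 min
#' tr$intensity[25] / tr$intensity[1]            # the I0/I_air ratio, 2.7
#' @export
forwardOxygenTrace <- function(trueOcr, cfg, sealed = TRUE, times = NULL,
                               purgeStart = NULL) {
  stopifnot(is(cfg, "SimConfig"), trueOcr >= 0)
  if (cfg@wellVolumePl <= 0 || cfg@oAirUm <= 0)
    stop("non-positive well volume or air-saturated oxygen concentration")
  if (is.null(times)) {
    times <- .frameTimes(cfg)
    if (is.null(purgeStart))
      purgeStart <- if (cfg@purgeFrames > 0L) cfg@nFrames + 1L else NA_integer_
  } else if (is.null(purgeStart)) purgeStart <- NA_integer_
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")

  k <- .kSvFromConfig(cfg)
  c0 <- .ocrToUmPerMin(trueOcr, cfg@wellVolumePl)
  lam <- cfg@leakRatePerMin
  isPurge <- if (is.na(purgeStart)) rep(FALSE, length(times))
             else seq_along(times) >= purgeStart
  tDraw <- times[!isPurge]

  if (sealed) {
    o2 <- pmax(0, cfg@oAirUm - c0 * tDraw)
    # sealed wells are insensitive to the purge: they hold their value
    o2 <- c(o2, rep(o2[length(o2)], sum(isPurge)))
  } else {
    # first-order exchange with ambient: dO2/dt = -c0 + lam * (amb - O2)
    o2 <- cfg@oAirUm - (c0 / lam) * (1 - exp(-lam * tDraw))
    o2 <- pmax(0, o2)
    if (any(isPurge)) {
      t0 <- times[which(isPurge)[1] - 1L]
      oStart <- o2[length(o2)]
      oSs <- cfg@purgeO2Um - c0 / lam
      tp <- times[isPurge] - t0
      o2p <- pmax(0, oSs + (oStart - oSs) * exp(-lam * tp))
      o2 <- c(o2, o2p)
    }
  }
  data.frame(time = times, o2Um = o2,
             intensity = cfg@baseCounts * cfg@o2Ratio / (1 + k * o2))
}

#' Forward model of a single well's pH-sensor trace
#'
#' The well acidifies linearly, `pH(t) = pHstart - ecar * t`, floored at
#' `cfg@phFloor`, and the sigmoid sensor model converts pH to normalized
#' emission intensity (see [phSigmoid()]); intensities are scaled so that the
#' first frame (assay-medium pH) equals `cfg@baseCounts`.
#'
#' @param trueEcar extracellular acidification rate, pH/min (>= 0).
#' @param cfg a [SimConfig-class].
#' @param times optional timestamps (minutes) replacing the config frame grid.
#' @return A data.frame with columns `time`, `ph` and `intensity`.
#' @examples
#' cfg <- simConfig(nFrames = 20, purgeFrames = 0)
#' tr <- forwardPhTrace(0.05, cfg)   # pH falls 7.4 -> 6.4 over 20 min
#' all(diff(tr$intensity) < 0)
#' @export
forwardPhTrace <- function(trueEcar, cfg, times = NULL) {
  stopifnot(is(cfg, "SimConfig"), trueEcar >= 0)
  p <- cfg@phParams
  if (p[["theta"]] <= 0) stop("degenerate pH sensor: theta must be > 0")
  if (is.null(times)) times <- .frameTimes(cfg)
  ph <- pmax(cfg@phFloor, cfg@phStart - trueEcar * times)
  iNorm <- phSigmoid(ph, p)
  data.frame(time = times, ph = ph,
             intensity = cfg@baseCounts * iNorm / phSigmoid(cfg@phStart, p))
}

# Truncated-Poisson sampler: values above `maxCells` are redrawn, which
# renormalizes the pmf on 0..maxCells.
.truncPois <- function(n, lambda, maxCells) {
  k <- rpois(n, lambda)
  while (any(k > maxCells)) {
    bad <- k > maxCells
    k[bad] <- rpois(sum(bad), lambda)
  }
  as.integer(k)
}

#' Random cell seeding of the microwell array
#'
#' Draws independent per-well cell counts from a Poisson law with mean
#' `cfg@seedingMean`, truncated at `cfg@maxCellsPerWell` by redrawing.
#' Deterministic given `cfg@rngSeed`.
#'
#' @param cfg a [SimConfig-class].
#' @return Integer vector of length `gridRows * gridCols` (row-major order).
#' @export
seedCells <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  nw <- cfg@gridRows * cfg@gridCols
  if (cfg@seedingMean == 0) return(integer(nw))
  set.seed(cfg@rngSeed)
  .truncPois(nw, cfg@seedingMean, cfg@maxCellsPerWell)
}

#' Generate a pH calibration series
#'
#' Evaluates the sigmoid sensor model over a pH grid (emulating a
#' Britton-Robinson buffer titration over pH 3-9), normalized to the
#' assay-medium point, optionally with multiplicative noise. The result is
#' suitable input for [fitPhSigmoid()].
#'
#' @param phParams named numeric `(i1, i2, pKa, theta)` (an `iRef` entry is
#'   ignored; the output is normalized).
#' @param phGrid pH values, all within 0-14.
#' @param noiseCv multiplicative noise CV (0 for a noise-free series).
#' @param mediumPh the assay-medium pH used as normalization anchor.
#' @return A data.frame with columns `ph` and `intensity`.
#' @examples
#' p <- c(i1 = 1.35, i2 = 0.27, pKa = 7, theta = 1)
#' cal <- makeCalibrationSeries(p, seq(3, 9, by = 0.5))
#' @export
makeCalibrationSeries <- function(phParams, phGrid, noiseCv = 0,
                                  mediumPh = 7.4) {
  if (length(phGrid) == 0L) stop("empty pH grid")
  if (any(phGrid < 0 | phGrid > 14)) stop("pH grid must lie within 0-14")
  iNorm <- phSigmoid(phGrid, phParams) / phSigmoid(mediumPh, phParams)
  if (noiseCv > 0)
    iNorm <- iNorm * (1 + noiseCv * rnorm(length(iNorm)))
  data.frame(ph = phGrid, intensity = iNorm)
}
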