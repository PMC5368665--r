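#' @import methods
#' @importFrom stats median mad quantile rnorm rpois rlnorm runif sd approx
#'   coef ks.test pt qt qnorm cor.test setNames
#' @importFrom utils head tail read.csv write.csv
NULL

#' Simulation configuration for synthetic microwell assays
#'
#' Holds every tunable of the forward model: array geometry, cell seeding,
#' per-cell rate laws, sensor physics, imaging noise and the seal-test purge
#' phase. Defaults describe a 64 x 64 array of 80 um diameter, 64.5 pL wells
#' imaged at 1-minute intervals with an oxygen sensor whose zero-oxygen to
#' air-saturated intensity ratio is 2.7.
#'
#' @slot gridRows,gridCols integer grid dimensions.
#' @slot wellRadiusUm well radius in micrometres.
#' @slot wellPitchUm centre-to-centre pitch in micrometres (hexagonal packing).
#' @slot wellVolumePl well volume in picolitres.
#' @slot pixelSizeUm micrometres per pixel of the rendered images.
#' @slot seedingMean expected cells per well (Poisson mean).
#' @slot maxCellsPerWell truncation point of the seeding law.
#' @slot ocrMedian,ocrGsd median (fmol/min) and geometric SD of the lognormal
#'   per-cell oxygen consumption rate law.
#' @slot ecarMedian,ecarGsd median (pH/min) and geometric SD of the lognormal
#'   per-cell extracellular acidification rate law.
#' @slot o2Ratio zero-oxygen to air-saturated intensity ratio I0/I_air.
#' @slot oAirUm dissolved oxygen at air saturation, micromolar.
#' @slot phParams named numeric (i1, i2, pKa, theta, iRef) of the sigmoid pH
#'   sensor model, in intensity units normalized to the assay medium.
#' @slot phStart,phFloor starting pH of the assay medium and the floor below
#'   which simulated acidification stops.
#' @slot noiseCv multiplicative per-pixel intensity noise (coefficient of
#'   variation).
#' @slot readNoise additive read noise SD, counts.
#' @slot gainFieldAmp amplitude of the smooth sensor-film heterogeneity field.
#' @slot photoDrift fractional intensity rise of empty sealed wells over the
#'   drawdown phase caused by photo-consumption of oxygen by the sensor.
#' @slot leakFraction,leakRatePerMin fraction of unsealed wells and their
#'   first-order equilibration rate with the ambient medium (1/min).
#' @slot defectFraction fraction of wells rendered with malformed lips and a
#'   sensor void.
#' @slot driftPxPerFrame rigid stage drift per frame, pixels (applied in x).
#' @slot frameIntervalMin minutes between frames.
#' @slot nFrames,purgeFrames number of drawdown frames and of terminal
#'   oxygen-purge (seal test) frames.
#' @slot purgeO2Um dissolved oxygen during the purge, micromolar.
#' @slot baseCounts nominal sensor intensity at air saturation, counts.
#' @slot rngSeed integer seed making the whole simulation reproducible.
#' @seealso [simConfig()] for the user-facing constructor.
#' @export
setClass("SimConfig", representation(
  gridRows = "integer", gridCols = "integer",
  wellRadiusUm = "numeric", wellPitchUm = "numeric", wellVolumePl = "numeric",
  pixelSizeUm = "numeric",
  seedingMean = "numeric", maxCellsPerWell = "integer",
  ocrMedian = "numeric", ocrGsd = "numeric",
  ecarMedian = "numeric", ecarGsd = "numeric",
  o2Ratio = "numeric", oAirUm = "numeric",
  phParams = "numeric", phStart = "numeric", phFloor = "numeric",
  noiseCv = "numeric", readNoise = "numeric", gainFieldAmp = "numeric",
  photoDrift = "numeric",
  leakFraction = "numeric", leakRatePerMin = "numeric",
  defectFraction = "numeric",
  driftPxPerFrame = "numeric",
  frameIntervalMin = "numeric", nFrames = "integer", purgeFrames = "integer",
  purgeO2Um = "numeric", baseCounts = "numeric", rngSeed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@gridRows < 1L || object@gridCols < 1L)
    msg <- c(msg, "grid dimensions must be >= 1")
  if (object@wellVolumePl <= 0) msg <- c(msg, "wellVolumePl must be > 0")
  if (object@oAirUm <= 0) msg <- c(msg, "oAirUm must be > 0")
  if (object@o2Ratio <= 1) msg <- c(msg, "o2Ratio (I0/I_air) must be > 1")
  if (object@leakFraction < 0 || object@leakFraction > 1)
    msg <- c(msg, "leakFraction must be in [0, 1]")
  if (object@defectFraction < 0 || object@defectFraction > 1)
    msg <- c(msg, "defectFraction must be in [0, 1]")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
  if (object@seedingMean < 0) msg <- c(msg, "seedingMean must be >= 0")
  if (!all(c("i1", "i2", "pKa", "theta") %in% names(object@phParams)))
    msg <- c(msg, "phParams must name i1, i2, pKa, theta")
  else {
    if (object@phParams[["i1"]] <= object@phParams[["i2"]])
      msg <- c(msg, "phParams: i1 must exceed i2")
    if (object@phParams[["theta"]] <= 0)
      msg <- c(msg, "phParams: theta must be > 0 (degenerate sensor)")
  }
  if (object@wellPitchUm <= object@wellRadiusUm)
    msg <- c(msg, "wellPitchUm must exceed wellRadiusUm (non-overlapping wells)")
  if (length(msg)) msg else TRUE
})

#' Geometric truth of a microwell array in pixel units
#'
#' @slot gridRows,gridCols integer grid dimensions.
#' @slot wellRadiusPx well radius, pixels.
#' @slot pitchPx centre-to-centre pitch, pixels.
#' @slot packing packing scheme; only `"hexagonal"` is supported.
#' @slot wellVolumePl well volume in picolitres.
#' @export
setClass("ArrayLayout", representation(
  gridRows = "integer", gridCols = "integer",
  wellRadiusPx = "numeric", pitchPx = "numeric",
  packing = "character", wellVolumePl = "numeric"
))

setValidity("ArrayLayout", function(object) {
  msg <- character(0)
  if (object@wellRadiusPx <= 0) msg <- c(msg, "wellRadiusPx must be > 0")
  if (object@pitchPx <= object@wellRadiusPx)
    msg <- c(msg, "pitchPx must exceed wellRadiusPx (wells non-overlapping)")
  if (object@wellVolumePl <= 0) msg <- c(msg, "wellVolumePl must be > 0")
  if (!identical(object@packing, "hexagonal"))
    msg <- c(msg, "only hexagonal packing is supported")
  if (length(msg)) msg else TRUE
})

#' Concentric extraction regions around a well centre
#'
#' Radii (pixels) of the centre disk, the lip annulus and the outside annulus
#' from which intensity statistics are read. Annuli must be ordered and
#' non-overlapping.
#'
#' @slot centerRadius,lipInner,lipOuter,outsideInner,outsideOuter numeric
#'   radii in pixels.
#' @seealso [regionSpec()]
#' @export
setClass("RegionSpec", representation(
  centerRadius = "numeric", lipInner = "numeric", lipOuter = "numeric",
  outsideInner = "numeric", outsideOuter = "numeric"
))

setValidity("RegionSpec", function(object) {
  ok <- object@centerRadius < object@lipInner &&
    object@lipInner < object@lipOuter &&
    object@lipOuter <= object@outsideInner &&
    object@outsideInner < object@outsideOuter
  if (ok) TRUE else "regions must satisfy center < lipIn < lipOut <= outIn < outOut"
})

#' Per-well, per-channel, per-region intensity time series
#'
#' The central trace container: 4-D arrays of region means and standard
#' deviations indexed `[well, channel, region, frame]`, with the acquisition
#' timestamps and the well table they were extracted for.
#'
#' @slot means,sds numeric arrays `[well, channel, region, frame]`; channels
#'   are `o2`, `ph`, `ref` and regions `center`, `lip`, `outside`.
#' @slot times acquisition timestamps, minutes, strictly increasing.
#' @slot purgeStart 1-based index of the first seal-test (purge) frame, or
#'   `NA` when the assay has no purge phase.
#' @slot wells the well table (one row per well: id, grid index, centre).
#' @export
setClass("WellTraces", representation(
  means = "array", sds = "array", times = "numeric",
  purgeStart = "integer", wells = "data.frame"
))

setValidity("WellTraces", function(object) {
  msg <- character(0)
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(dim(object@means)) != 4L)
    msg <- c(msg, "means must be a 4-D array [well, channel, region, frame]")
  if (!identical(dim(object@means), dim(object@sds)))
    msg <- c(msg, "means and sds must have identical dimensions")
  if (any(object@sds < 0, na.rm = TRUE)) msg <- c(msg, "sds must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Stern-Volmer oxygen sensor calibration
#'
#' Parameters of the quenching law `I0 / I = 1 + kSv * [O2]`.
#'
#' @slot kSv Stern-Volmer constant, 1/uM.
#' @slot i0 emission intensity at zero oxygen.
#' @slot oAirUm dissolved oxygen at air saturation, uM.
#' @slot source one of `two_point`, `local_well`, `assay_average`.
#' @export
setClass("O2Calibration", representation(
  kSv = "numeric", i0 = "numeric", oAirUm = "numeric", source = "character"
))

setValidity("O2Calibration", function(object) {
  msg <- character(0)
  if (object@kSv < 0) msg <- c(msg, "kSv must be >= 0")
  if (object@i0 <= 0) msg <- c(msg, "i0 must be > 0")
  if (object@oAirUm <= 0) msg <- c(msg, "oAirUm must be > 0")
  if (!object@source %in% c("two_point", "local_well", "assay_average"))
    msg <- c(msg, "unknown calibration source")
  if (length(msg)) msg else TRUE
})

#' Sigmoid pH sensor calibration
#'
#' Parameters of `I(pH) = i2 + (i1 - i2) / (1 + 10^(theta * (pKa - pH)))`
#' with intensities normalized to the assay-medium point.
#'
#' @slot i1,i2 maximum and minimum normalized intensity of the dynamic range.
#' @slot pKa acid dissociation constant, pH units.
#' @slot theta sensitivity, 1/pH.
#' @slot iRef sensor intensity in the standard assay medium (the
#'   normalization anchor).
#' @slot rms root-mean-square residual of the fit (0 for exact parameters).
#' @export
setClass("PHCalibration", representation(
  i1 = "numeric", i2 = "numeric", pKa = "numeric", theta = "numeric",
  iRef = "numeric", rms = "numeric"
))

setValidity("PHCalibration", function(object) {
  msg <- character(0)
  if (object@i1 <= object@i2) msg <- c(msg, "i1 must exceed i2")
  if (object@theta <= 0) msg <- c(msg, "theta must be > 0")
  if (object@iRef <= 0) msg <- c(msg, "iRef must be > 0")
  if (length(msg)) msg else TRUE
})

#' Non-reflective similarity transform between two point sets
#'
#' Maps points `p` to `scale * R(rotation) %*% p + translation` with the
#' rotation constrained orientation-preserving (positive determinant), as
#' used to carry 4X assay well coordinates into the 10X cell-count images.
#'
#' @slot scale positive scale factor.
#' @slot rotation rotation angle, radians.
#' @slot translation length-2 numeric (tx, ty), pixels.
#' @slot rms root-mean-square residual of the fit.
#' @export
setClass("SimilarityTransform", representation(
  scale = "numeric", rotation = "numeric", translation = "numeric",
  rms = "numeric"
))

setValidity("SimilarityTransform", function(object) {
  msg <- character(0)
  if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
  if (length(object@translation) != 2L)
    msg <- c(msg, "translation must have length 2")
  if (length(msg)) msg else TRUE
})

#' A complete simulated assay
#'
#' Output of [renderAssay()]: rendered image stacks for the three spectral
#' channels, the high-magnification nuclei image set, the hidden per-well
#' ground truth, timestamps and provenance.
#'
#' @slot stacks named list of numeric arrays `[height, width, frame]` for
#'   channels `o2`, `ph` and `ref`.
#' @slot nuclei nuclei-stain image at cell-count magnification (matrix).
#' @slot nucleiRef well-pattern reference image at the same magnification.
#' @slot truth ground-truth data.frame (well, row, col, x, y, cellCount,
#'   trueOcr, trueEcar, sealed, defective).
#' @slot times frame timestamps, minutes.
#' @slot purgeStart 1-based index of the first purge frame (`NA` if none).
#' @slot drift per-frame cumulative rigid translation (frame, dx, dy).
#' @slot nucleiScale magnification ratio of the nuclei images relative to the
#'   assay stacks.
#' @slot config the [SimConfig-class] that produced the assay.
#' @slot layout the pixel-space [ArrayLayout-class].
#' @export
setClass("SimulatedAssay", representation(
  stacks = "list", nuclei = "matrix", nucleiRef = "matrix",
  truth = "data.frame", times = "numeric", purgeStart = "integer",
  drift = "data.frame", nucleiScale = "numeric",
  config = "SimConfig", layout = "ArrayLayout"
))

# ---- show methods -----------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d x %d wells, r=%.0f um, pitch=%.0f um, %.1f pL, %.1f um/px\n",
    object@gridRows, object@gridCols, object@wellRadiusUm,
    object@wellPitchUm, object@wellVolumePl, object@pixelSizeUm))
  cat(sprintf(
    "  seeding %.2f cells/well; OCR median %.2f fmol/min (GSD %.2f); ECAR median %.3f pH/min (GSD %.2f)\n",
    object@seedingMean, object@ocrMedian, object@ocrGsd,
    object@ecarMedian, object@ecarGsd))
  cat(sprintf(
    "  I0/Iair %.2f, [O_air] %.0f uM; noise CV %.3f; leak %.2f; defects %.2f; %d + %d frames @ %.1f min\n",
    object@o2Ratio, object@oAirUm, object@noiseCv, object@leakFraction,
    object@defectFraction, object@nFrames, object@purgeFrames,
    object@frameIntervalMin))
})

setMethod("show", "ArrayLayout", function(object) {
  cat(sprintf("ArrayLayout: %d x %d %s wells, r=%.1f px, pitch=%.1f px, %.1f pL\n",
              object@gridRows, object@gridCols, object@packing,
              object@wellRadiusPx, object@pitchPx, object@wellVolumePl))
})

setMethod("show", "WellTraces", function(object) {
  d <- dim(object@means)
  cat(sprintf("WellTraces: %d wells x %d channels x %d regions x %d frames",
              d[1], d[2], d[3], d[4]))
  if (!is.na(object@purgeStart))
    cat(sprintf(" (purge from frame %d)", object@purgeStart))
  cat("\n")
})

setMethod("show", "O2Calibration", function(object) {
  cat(sprintf("O2Calibration (%s): kSv = %.5g 1/uM, I0 = %.4g, [O_air] = %.0f uM\n",
              object@source, object@kSv, object@i0, object@oAirUm))
})

setMethod("show", "PHCalibration", function(object) {
  cat(sprintf(
    "PHCalibration: i1 = %.4g, i2 = %.4g, pKa = %.3f, theta = %.3f, iRef = %.4g (fit rms %.3g)\n",
    object@i1, object@i2, object@pKa, object@theta, object@iRef, object@rms))
})

setMethod("show", "SimilarityTransform", function(object) {
  cat(sprintf(
    "SimilarityTransform: scale %.4f, rotation %.4f rad, translation (%.2f, %.2f), rms %.3g\n",
    object@scale, object@rotation, object@translation[1],
    object@translation[2], object@rms))
})

setMethod("show", "SimulatedAssay", function(object) {
  d <- dim(object@stacks$ref)
  cat(sprintf(
    "SimulatedAssay: %d wells, %d x %d px, %d frames (purge from %s), nuclei at %.1fx\n",
    nrow(object@truth), d[1], d[2], d[3],
    ifelse(is.na(object@purgeStart), "none", object@purgeStart),
    object@nucleiScale))
})

# ---- accessors --------------------------------------------------------------

#' Accessors for simulated assays and trace containers
#'
#' `groundTruth()` returns the hidden per-well parameter table of a simulated
#' assay; `imageStack()` one channel's `[h, w, frame]` array; `frameTimes()`
#' the timestamps; `nWells()` the number of wells; `traceMatrix()` a
#' `[well, frame]` matrix of region means for one channel/region pair.
#'
#' @param object a [SimulatedAssay-class] or [WellTraces-class].
#' @param channel one of `"o2"`, `"ph"`, `"ref"`.
#' @param region one of `"center"`, `"lip"`, `"outside"`.
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setMethod("groundTruth", "SimulatedAssay", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("imageStack", function(object, channel) standardGeneric("imageStack"))

#' @rdname accessors
#' @export
setMethod("imageStack", "SimulatedAssay", function(object, channel) {
  stopifnot(channel %in% names(object@stacks))
  object@stacks[[channel]]
})

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setMethod("frameTimes", "SimulatedAssay", function(object) object@times)

#' @rdname accessors
#' @export
setMethod("frameTimes", "WellTraces", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("nWells", function(object) standardGeneric("nWells"))

#' @rdname accessors
#' @export
setMethod("nWells", "SimulatedAssay", function(object) nrow(object@truth))

#' @rdname accessors
#' @export
setMethod("nWells", "WellTraces", function(object) dim(object@means)[1])

#' @rdname accessors
#' @export
setGeneric("traceMatrix", function(object, channel, region)
  standardGeneric("traceMatrix"))

#' @rdname accessors
#' @export
setMethod("traceMatrix", "WellTraces", function(object, channel, region) {
  object@means[, channel, region, , drop = TRUE]
})

#' @rdname accessors
#' @param x a [WellTraces-class].
#' @export
wellTable <- function(x) {
  stopifnot(is(x, "WellTraces"))
  x@wells
}
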