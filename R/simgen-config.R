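#' Build a simulation configuration
#'
#' Constructs a validated [SimConfig-class]. Defaults encode the study
#' conditions of the assay the generator emulates: a 64 x 64 hexagonally
#' packed array of 80 um diameter, 64.5 pL wells; Poisson seeding tuned to a
#' ~17% single-cell occupancy; lognormal per-cell OCR (median 0.80 fmol/min,
#' geometric SD 1.8) and ECAR (median 0.010 pH/min); an oxygen sensor with
#' I0/I_air = 2.7 at 200 uM air-saturated oxygen; 2% multiplicative imaging
#' noise; 30% leaky wells; 5% defective wells; a 7% empty-well intensity
#' drift from sensor photo-consumption; and a terminal oxygen-purge seal
#' test.
#'
#' @param gridRows,gridCols grid dimensions.
#' @param wellRadiusUm,wellPitchUm,wellVolumePl well geometry (um, um, pL).
#' @param pixelSizeUm rendered pixel size, um/px.
#' @param seedingMean expected cells/well of the truncated Poisson seeding law.
#' @param maxCellsPerWell truncation point of the seeding law.
#' @param ocrMedian,ocrGsd lognormal per-cell OCR law (fmol/min, geometric SD).
#' @param ecarMedian,ecarGsd lognormal per-cell ECAR law (pH/min, geometric SD).
#' @param o2Ratio I0/I_air intensity ratio of the oxygen sensor.
#' @param oAirUm dissolved oxygen at air saturation, uM.
#' @param phParams named numeric `(i1, i2, pKa, theta, iRef)` of the sigmoid
#'   pH model, normalized to the assay medium.
#' @param phStart,phFloor assay-medium pH and the acidification floor.
#' @param noiseCv multiplicative per-pixel noise CV.
#' @param readNoise additive read-noise SD, counts.
#' @param gainFieldAmp amplitude of the smooth film-heterogeneity gain field.
#' @param photoDrift fractional oxygen-channel intensity rise of empty sealed
#'   wells over the drawdown phase.
#' @param leakFraction,leakRatePerMin unsealed-well fraction and their
#'   first-order exchange rate with the ambient medium (1/min).
#' @param defectFraction fraction of wells rendered malformed.
#' @param driftPxPerFrame rigid stage drift per frame, px.
#' @param frameIntervalMin minutes between frames.
#' @param nFrames,purgeFrames drawdown and seal-test frame counts.
#' @param purgeO2Um dissolved oxygen during the purge, uM.
#' @param baseCounts nominal air-saturated sensor intensity, counts.
#' @param rngSeed integer seed.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(gridRows = 8, gridCols = 8, nFrames = 20)
#' cfg
#' @export
simConfig <- function(gridRows = 64L, gridCols = 64L,
                      wellRadiusUm = 40, wellPitchUm = 200,
                      wellVolumePl = 64.5, pixelSizeUm = 8,
                      seedingMean = 0.22, maxCellsPerWell = 8L,
                      ocrMedian = 0.80, ocrGsd = 1.8,
                      ecarMedian = 0.010, ecarGsd = 1.8,
                      o2Ratio = 2.7, oAirUm = 200,
                      phParams = c(i1 = 1.35, i2 = 0.27, pKa = 7.0,
                                   theta = 1.0, iRef = 1.0),
                      phStart = 7.4, phFloor = 6.0,
                      noiseCv = 0.02, readNoise = 0,
                      gainFieldAmp = 0.05, photoDrift = 0.07,
                      leakFraction = 0.3, leakRatePerMin = 0.2,
                      defectFraction = 0.05,
                      driftPxPerFrame = 0,
                      frameIntervalMin = 1, nFrames = 70L, purgeFrames = 10L,
                      purgeO2Um = 900, baseCounts = 1000,
                      rngSeed = 1L) {
  new("SimConfig",
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      wellRadiusUm = wellRadiusUm, wellPitchUm = wellPitchUm,
      wellVolumePl = wellVolumePl, pixelSizeUm = pixelSizeUm,
      seedingMean = seedingMean, maxCellsPerWell = as.integer(maxCellsPerWell),
      ocrMedian = ocrMedian, ocrGsd = ocrGsd,
      ecarMedian = ecarMedian, ecarGsd = ecarGsd,
      o2Ratio = o2Ratio, oAirUm = oAirUm,
      phParams = phParams, phStart = phStart, phFloor = phFloor,
      noiseCv = noiseCv, readNoise = readNoise, gainFieldAmp = gainFieldAmp,
      photoDrift = photoDrift,
      leakFraction = leakFraction, leakRatePerMin = leakRatePerMin,
      defectFraction = defectFraction,
      driftPxPerFrame = driftPxPerFrame,
      frameIntervalMin = frameIntervalMin,
      nFrames = as.integer(nFrames), purgeFrames = as.integer(purgeFrames),
      purgeO2Um = purgeO2Um, baseCounts = baseCounts,
      rngSeed = as.integer(rngSeed))
}

#' Pixel-space array layout implied by a simulation configuration
#'
#' @param cfg a [SimConfig-class].
#' @return An [ArrayLayout-class] with radii and pitch converted to pixels.
#' @export
layoutFromConfig <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  new("ArrayLayout",
      gridRows = cfg@gridRows, gridCols = cfg@gridCols,
      wellRadiusPx = cfg@wellRadiusUm / cfg@pixelSizeUm,
      pitchPx = cfg@wellPitchUm / cfg@pixelSizeUm,
      packing = "hexagonal", wellVolumePl = cfg@wellVolumePl)
}

#' Construct an array layout directly
#'
#' @param gridRows,gridCols grid dimensions.
#' @param wellRadiusPx,pitchPx geometry in pixels.
#' @param wellVolumePl well volume, pL.
#' @return An [ArrayLayout-class].
#' @export
arrayLayout <- function(gridRows, gridCols, wellRadiusPx, pitchPx,
                        wellVolumePl = 64.5) {
  new("ArrayLayout",
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      wellRadiusPx = wellRadiusPx, pitchPx = pitchPx,
      packing = "hexagonal", wellVolumePl = wellVolumePl)
}

#' Read / write a simulation configuration as YAML or JSON
#'
#' Field names in the file mirror the arguments of [simConfig()].
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @param cfg a [SimConfig-class] (for writing).
#' @return `readSimConfig()` returns a [SimConfig-class];
#'   `writeSimConfig()` returns `path` invisibly.
#' @export
readSimConfig <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(vals$phParams)) vals$phParams <- unlist(vals$phParams)
  do.call(simConfig, vals)
}

#' @rdname readSimConfig
#' @export
writeSimConfig <- function(cfg, path) {
  stopifnot(is(cfg, "SimConfig"))
  vals <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(vals) <- slotNames(cfg)
  vals$phParams <- as.list(vals$phParams)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(vals, path)
  invisible(path)
}
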