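# Shared synthetic fixtures, built once per session and cached.

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, builder(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# A small assay at the default study conditions (30% leaky, 5% defective,
# 2% noise, random seeding) used for detection, QC and seal tests.
fxDefaultAssay <- function() {
  .cached("defaultAssay", function() {
    cfg <- simConfig(gridRows = 12, gridCols = 12, nFrames = 40,
                     purgeFrames = 10, seedingMean = 0.4, rngSeed = 7)
    sim <- renderAssay(cfg, nuclei = FALSE)
    loci <- detectWells(sim@stacks$ref[, , 1], sim@layout)
    list(sim = sim, loci = loci,
         match = matchWellsToTruth(loci, groundTruth(sim),
                                   sim@layout@pitchPx / 4))
  })
}

# A single-cell cohort (all wells hold exactly one cell) analysed end to end.
fxCohort <- function() {
  .cached("cohort", function() {
    cfg <- simConfig(gridRows = 6, gridCols = 10, nFrames = 60,
                     purgeFrames = 8, seedingMean = 0, leakFraction = 0,
                     defectFraction = 0, ocrMedian = 0.46, rngSeed = 11)
    sim <- renderAssay(cfg, cellCounts = rep(1L, 60))
    res <- analyzeAssay(sim)
    list(sim = sim, res = res,
         match = matchWellsToTruth(res$loci, groundTruth(sim),
                                   sim@layout@pitchPx / 4))
  })
}

# Mixed-occupancy nuclei fixture (0-7 cells per well) for counting tests.
fxNucleiSet <- function() {
  .cached("nucleiSet", function() {
    cfg <- simConfig(gridRows = 10, gridCols = 10, nFrames = 2,
                     purgeFrames = 0, seedingMean = 0, leakFraction = 0,
                     defectFraction = 0, rngSeed = 3)
    cc <- as.integer(rep(0:7, length.out = 100))
    sim <- renderAssay(cfg, cellCounts = cc)
    tr <- groundTruth(sim)
    sc <- sim@nucleiScale
    wells <- data.frame(wellId = tr$well, x = tr$x * sc, y = tr$y * sc)
    segs <- segmentWells(sim@nuclei, wells, 16L)
    list(sim = sim, trueCounts = cc, wells = wells, segs = segs)
  })
}

# Direct (image-free) forward traces with additive noise at the region level,
# for calibration tests that do not need rendered frames.
makeTraceMatrix <- function(ocrs, cfg, noiseSd = 0, seed = 1) {
  set.seed(seed)
  nT <- cfg@nFrames + cfg@purgeFrames
  m <- matrix(0, length(ocrs), nT)
  for (i in seq_along(ocrs))
    m[i, ] <- forwardOxygenTrace(ocrs[i], cfg)$intensity
  if (noiseSd > 0) m <- m * (1 + noiseSd * matrix(rnorm(length(m)), nrow(m)))
  m
}
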