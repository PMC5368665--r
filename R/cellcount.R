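# Nuclei counting from the high-magnification stained image set: adaptive
# well-pattern subtraction, Laplacian-of-Gaussian blob detection, and
# parameter tuning against labelled fixtures.

#' Subtract the well-associated pattern from a segment
#'
#' The mean of all segmentation images captures the well-associated
#' artifacts (lip, film texture); it is scaled to each segment's average
#' intensity before subtraction, so the residual isolates the cells
#' regardless of the segment's bulk brightness. Negative residuals clip to
#' zero.
#'
#' @param segment one well crop (matrix).
#' @param pattern the mean segment image (same shape).
#' @return Cell-only residual image.
#' @export
subtractWellPattern <- function(segment, pattern) {
  if (!identical(dim(segment), dim(pattern)))
    stop("segment and pattern shapes differ")
  mp <- mean(pattern)
  if (mp <= 0) stop("degenerate pattern: non-positive mean")
  scale <- mean(segment) / mp
  pmax(segment - scale * pattern, 0)
}

#' Default nuclei-counting parameters
#'
#' @param sigma LoG blob scale, px (the nucleus radius at the counting
#'   magnification).
#' @param threshold minimum blob response, relative to the segment's
#'   reference intensity scale.
#' @param minSep merge radius: candidate maxima closer than this collapse to
#'   the stronger one, px.
#' @return Named list of parameters.
#' @export
countParams <- function(sigma = 1.6, threshold = 10, minSep = 4) {
  list(sigma = sigma, threshold = threshold, minSep = minSep)
}

#' Count nuclei in a cell-only image
#'
#' Laplacian-of-Gaussian blob detection: the image (scaled by `scaleRef` so
#' counting is invariant to global intensity) is convolved with a
#' scale-normalized -LoG kernel; local maxima above `threshold` are blob
#' candidates, candidates within `minSep` merge to the brighter peak (ties
#' to the higher image intensity), and the survivors are the nuclei.
#'
#' @param img residual image from [subtractWellPattern()].
#' @param params parameter list from [countParams()].
#' @param scaleRef intensity normalization (typically the mean of the raw
#'   segment before subtraction); `NULL` uses the image maximum with a
#'   floor, keeping empty images at zero counts.
#' @return list(`count`, `centers` data.frame(x, y, response),
#'   `quality` = weakest accepted response over the threshold).
#' @export
countNuclei <- function(img, params = countParams(), scaleRef = NULL) {
  if (length(img) == 0L || all(img <= 0))
    return(list(count = 0L,
                centers = data.frame(x = numeric(0), y = numeric(0),
                                     response = numeric(0)),
                quality = NA_real_))
  if (is.null(scaleRef)) scaleRef <- max(mean(img), 1e-12)
  z <- img / scaleRef
  resp <- .xcorr2(z, -.logKernel(params$sigma))
  peaks <- .localMaxima(resp, params$threshold)
  if (nrow(peaks) == 0L)
    return(list(count = 0L,
                centers = data.frame(x = numeric(0), y = numeric(0),
                                     response = numeric(0)),
                quality = NA_real_))
  # merge candidates within the nucleus radius, keeping the stronger
  ord <- order(-peaks$value,
               -z[cbind(peaks$y + 1L, peaks$x + 1L)])
  peaks <- peaks[ord, , drop = FALSE]
  kept <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (i == 1L) { kept[1] <- TRUE; next }
    prev <- which(kept)
    d2 <- (peaks$x[prev] - peaks$x[i])^2 + (peaks$y[prev] - peaks$y[i])^2
    kept[i] <- all(d2 >= params$minSep^2)
  }
  centers <- peaks[kept, , drop = FALSE]
  list(count = nrow(centers),
       centers = data.frame(x = centers$x, y = centers$y,
                            response = centers$value),
       quality = min(centers$value) / params$threshold)
}

#' Count nuclei for every well of a cell-count image
#'
#' Segments the nuclei image at the (transformed) well coordinates, builds
#' the mean well pattern, subtracts it adaptively per well and runs LoG blob
#' detection on each residual.
#'
#' @param nucImage nuclei-stain image at counting magnification.
#' @param wells well table with `x`, `y` centers in nuclei-image pixels
#'   (apply the 4X to 10X transform first; see [fitSimilarityTransform()]).
#' @param halfSize segment half-width, px.
#' @param params parameter list from [countParams()].
#' @return data.frame (`wellId`, `count`, `quality`).
#' @export
countWellNuclei <- function(nucImage, wells, halfSize, params = countParams()) {
  segs <- segmentWells(nucImage, wells, halfSize)
  pattern <- buildReferenceWell(segs)
  # buildReferenceWell normalizes to mean 1; restore the intensity scale
  valid <- apply(segs, 3, function(s) !any(is.na(s)))
  patScale <- mean(apply(segs[, , valid, drop = FALSE], 3, mean))
  pattern <- pattern * patScale
  n <- dim(segs)[3]
  counts <- integer(n)
  quality <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- segs[, , i]
    if (any(is.na(s))) { counts[i] <- NA_integer_; next }
    resid <- subtractWellPattern(s, pattern)
    # the pattern mean tracks global intensity but not per-well occupancy,
    # so blob responses are comparable across wells
    res <- countNuclei(resid, params, scaleRef = patScale)
    counts[i] <- res$count
    quality[i] <- res$quality
  }
  data.frame(wellId = if (!is.null(wells$wellId)) wells$wellId
             else seq_len(n) - 1L,
             count = counts, quality = quality)
}

#' Tune counting parameters against labelled fixtures
#'
#' Constrained minimization of the number of false cell counts over a
#' bounded parameter box: multi-start coordinate descent with a per-axis
#' grid, starting from the supplied incumbent and from the box centre. The
#' incumbent is always a candidate, so the tuned error never exceeds the
#' incumbent's.
#'
#' @param fixtures list of `list(img, trueCount, scaleRef)` labelled
#'   examples (residual images with known counts).
#' @param bounds named list of `c(lower, upper)` per tunable parameter
#'   (subset of `sigma`, `threshold`, `minSep`).
#' @param start incumbent parameter list; default [countParams()].
#' @param nGrid grid points per axis and sweep.
#' @param nSweeps coordinate-descent sweeps per start.
#' @return list(`params`, `error` = total absolute count error).
#' @export
tuneParameters <- function(fixtures, bounds, start = countParams(),
                           nGrid = 7L, nSweeps = 3L) {
  if (length(fixtures) == 0L) stop("empty fixture set")
  objective <- function(p) {
    sum(vapply(fixtures, function(f) {
      res <- countNuclei(f$img, p, scaleRef = f$scaleRef)
      abs(res$count - f$trueCount)
    }, numeric(1)))
  }
  clampToBox <- function(p) {
    for (nm in names(bounds))
      p[[nm]] <- min(max(p[[nm]], bounds[[nm]][1]), bounds[[nm]][2])
    p
  }
  mid <- start
  for (nm in names(bounds)) mid[[nm]] <- mean(bounds[[nm]])
  bestP <- clampToBox(start)
  bestE <- objective(bestP)
  for (p0 in list(clampToBox(start), mid)) {
    p <- p0
    e <- objective(p)
    for (sweep in seq_len(nSweeps)) {
      for (nm in names(bounds)) {
        grid <- seq(bounds[[nm]][1], bounds[[nm]][2], length.out = nGrid)
        for (g in grid) {
          cand <- p; cand[[nm]] <- g
          ce <- objective(cand)
          if (ce < e) { e <- ce; p <- cand }
        }
      }
      if (e == 0) break
    }
    if (e < bestE) { bestE <- e; bestP <- p }
  }
  list(params = bestP, error = bestE)
}
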