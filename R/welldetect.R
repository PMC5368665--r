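# Well detection: illumination flattening, lip binarization, circular Hough
# detection in both polarities, duplicate consolidation, hexagonal-grid
# filtering, rigid tracking and 4X -> 10X similarity registration.

#' Correct non-uniform illumination
#'
#' Estimates the large-scale gain field by heavy Gaussian blurring and
#' divides it out; the result is mean-normalized to 1. Removes illumination
#' gradients and smooth sensor-concentration gradients before binarization.
#'
#' @param image 2-D non-negative numeric matrix.
#' @param sigmaPx Gaussian blur scale of the field estimate, pixels; choose
#'   large relative to the well pitch (default 48).
#' @param method `"gaussian"` (heavy blur; robust on arbitrary smooth
#'   fields) or `"poly"` (order-2 polynomial least squares; exact on
#'   low-order fields, free of blur edge bias).
#' @return Corrected matrix with mean exactly 1.
#' @export
flattenIllumination <- function(image, sigmaPx = 48,
                                method = c("gaussian", "poly")) {
  stopifnot(is.matrix(image), all(image >= 0))
  method <- match.arg(method)
  if (max(image) == 0) stop("constant-zero image: no illumination to flatten")
  if (method == "gaussian") {
    sigmaPx <- min(sigmaPx, (min(dim(image)) - 1) / 8)  # kernel must fit
    field <- as.matrix(EBImage::gblur(image, sigma = sigmaPx,
                                      boundary = "replicate"))
  } else {
    xs <- seq(-1, 1, length.out = ncol(image))
    ys <- seq(-1, 1, length.out = nrow(image))
    X <- cbind(1,
               rep(xs, each = nrow(image)), rep(ys, times = ncol(image)),
               rep(xs, each = nrow(image)) * rep(ys, times = ncol(image)),
               rep(xs^2, each = nrow(image)), rep(ys^2, times = ncol(image)))
    cf <- stats::lm.fit(X, as.vector(image))$coefficients
    field <- matrix(X %*% cf, nrow(image), ncol(image))
  }
  field[field <= 0] <- min(field[field > 0])
  out <- image / field
  out / mean(out)
}

#' Binarize well lips by area-matched thresholding
#'
#' Selects the intensity threshold so that the white-pixel fraction of the
#' mask equals the fractional surface area of the well lips implied by the
#' array geometry (to within one quantile step; ties broken toward the
#' higher threshold). Invariant to global intensity scaling.
#'
#' @param image corrected 2-D image (see [flattenIllumination()]).
#' @param layout an [ArrayLayout-class]; supplies the well count and radius.
#' @param lipInner,lipOuter lip annulus radii as fractions of the well
#'   radius.
#' @return Logical matrix of the same dimensions.
#' @export
binarizeLips <- function(image, layout, lipInner = 0.88, lipOuter = 1.15) {
  stopifnot(is.matrix(image), is(layout, "ArrayLayout"))
  if (max(image) == min(image))
    stop("degenerate (constant) image: lip fraction is undefined")
  r <- layout@wellRadiusPx
  lipArea <- pi * r^2 * (lipOuter^2 - lipInner^2)
  frac <- layout@gridRows * layout@gridCols * lipArea / length(image)
  frac <- min(max(frac, 1e-6), 0.5)
  thr <- quantile(image, 1 - frac, names = FALSE, type = 7)
  mStrict <- image > thr
  mLoose <- image >= thr
  # pick the mask whose white fraction is closer to the target; on a tie the
  # stricter mask (higher effective threshold) wins
  dStrict <- abs(mean(mStrict) - frac)
  dLoose <- abs(mean(mLoose) - frac)
  if (dStrict <= dLoose) mStrict else mLoose
}

#' Detect circular well candidates by circular Hough transform
#'
#' Template-free detection: every foreground pixel votes for circle centers
#' at each radius via FFT cross-correlation with one-pixel-thick ring
#' kernels. Both polarities are scanned - the bright lip pixels themselves
#' (light circular features) and the boundary pixels of the dark complement
#' (dark circular features) - and candidates from both passes are
#' concatenated. Accumulators are normalized by ring circumference and
#' smoothed by one pixel, so confidence is the fraction of the ring
#' supported by foreground.
#'
#' @param mask logical matrix from [binarizeLips()].
#' @param radii integer-ish vector of candidate radii (pixels) bracketing the
#'   well radius.
#' @param relThreshold candidates must exceed this fraction of the strongest
#'   accumulator peak of their polarity.
#' @return data.frame (`x`, `y`, `radiusPx`, `confidence`, `polarity`); empty
#'   when the mask is blank.
#' @export
detectCircles <- function(mask, radii, relThreshold = 0.5) {
  stopifnot(is.matrix(mask))
  m <- mask * 1.0
  if (sum(m) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), radiusPx = numeric(0),
                      confidence = numeric(0), polarity = character(0)))
  # dark-feature pass votes from the complement's boundary pixels
  dil <- m
  for (dy in -1:1) for (dx in -1:1)
    dil <- pmax(dil, .shiftMatrix(m, dx, dy, fill = 0))
  darkEdge <- (dil > 0) & (m == 0)
  smooth3 <- matrix(1 / 9, 3, 3)
  out <- list()
  for (pol in c("light", "dark")) {
    src <- if (pol == "light") m else darkEdge * 1.0
    if (sum(src) == 0) next
    cand <- list()
    for (r in radii) {
      ring <- .ringKernel(r)
      acc <- .xcorr2(src, ring) / sum(ring)
      acc <- .xcorr2(acc, smooth3)
      cand[[length(cand) + 1L]] <-
        cbind(.localMaxima(acc, 0), radiusPx = r)
    }
    cand <- do.call(rbind, cand)
    if (nrow(cand) == 0L) next
    keep <- cand$value > relThreshold * max(cand$value)
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) > 0L)
      out[[pol]] <- data.frame(x = cand$x, y = cand$y,
                               radiusPx = cand$radiusPx,
                               confidence = cand$value, polarity = pol)
  }
  if (length(out) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), radiusPx = numeric(0),
                      confidence = numeric(0), polarity = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Consolidate duplicate circle detections
#'
#' Candidates closer than `minSeparation` are merged into a single locus:
#' groups are the connected components of the within-cutoff proximity graph
#' (single-linkage clustering cut at `minSeparation`); each group collapses
#' to its confidence-weighted mean center with confidence equal to the
#' maximum of its members. Idempotent on its own output.
#'
#' @param candidates data.frame with columns `x`, `y`, `confidence` and
#'   optionally `radiusPx`.
#' @param minSeparation merge radius, pixels (typically pitch / 2).
#' @return data.frame of consolidated loci (`x`, `y`, `radiusPx`,
#'   `confidence`, `nMerged`).
#' @export
consolidateDetections <- function(candidates, minSeparation) {
  stopifnot(minSeparation > 0)
  n <- nrow(candidates)
  if (n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), radiusPx = numeric(0),
                      confidence = numeric(0), nMerged = integer(0)))
  if (is.null(candidates$radiusPx)) candidates$radiusPx <- NA_real_
  comp <- .linkComponents(candidates$x, candidates$y, minSeparation)
  wsum <- rowsum(candidates$confidence, comp)
  wx <- rowsum(candidates$confidence * candidates$x, comp) / wsum
  wy <- rowsum(candidates$confidence * candidates$y, comp) / wsum
  wr <- rowsum(candidates$confidence * candidates$radiusPx, comp) / wsum
  cmax <- vapply(split(candidates$confidence, comp), max, numeric(1))
  cnt <- as.integer(table(comp))
  data.frame(x = as.numeric(wx), y = as.numeric(wy),
             radiusPx = as.numeric(wr), confidence = as.numeric(cmax),
             nMerged = cnt)
}

#' Filter detections against the hexagonal array geometry
#'
#' Fits a hexagonal lattice to the detected centers - pitch from
#' nearest-neighbour distances, orientation from nearest-neighbour angles
#' folded to the 60-degree sector, then a least-squares affine refinement -
#' assigns every locus to its nearest lattice node, and discards loci
#' farther than `tolerance` from any node. When several loci claim one node
#' the highest confidence wins (ties to the smaller distance).
#'
#' @param loci data.frame with `x`, `y`, `confidence` columns.
#' @param layout an [ArrayLayout-class] (pitch prior and grid size).
#' @param tolerance maximum node distance, pixels (default pitch / 4).
#' @return `loci` with `row`, `col`, `wellId` and `gridResidual` added and
#'   outliers removed.
#' @export
enforceGrid <- function(loci, layout, tolerance = NULL) {
  stopifnot(is(layout, "ArrayLayout"))
  if (nrow(loci) < 4L) stop("too few loci to fit a lattice (need >= 4)")
  if (is.null(tolerance)) tolerance <- layout@pitchPx / 4

  nn <- .nearestNeighbor(loci$x, loci$y, 1.6 * layout@pitchPx)
  has <- !is.na(nn$idx)
  if (sum(has) < 4L) stop("too few neighbouring loci to estimate the lattice")
  pitch <- median(nn$dist[has])
  dx <- loci$x[nn$idx[has]] - loci$x[has]
  dy <- loci$y[nn$idx[has]] - loci$y[has]
  ang <- (atan2(dy, dx) * 180 / pi) %% 60
  ang[ang >= 30] <- ang[ang >= 30] - 60
  theta <- median(ang) * pi / 180

  a1 <- pitch * c(cos(theta), sin(theta))
  a2 <- pitch * c(cos(theta + pi / 3), sin(theta + pi / 3))
  B <- cbind(a1, a2)
  origin <- which.min((loci$x - mean(loci$x))^2 + (loci$y - mean(loci$y))^2)
  p0 <- c(loci$x[origin], loci$y[origin])

  for (iter in 1:2) {
    nIdx <- round(solve(B, rbind(loci$x - p0[1], loci$y - p0[2])))
    # least-squares refinement of basis and offset given the assignment
    fitX <- stats::lm.fit(cbind(1, t(nIdx)), loci$x)
    fitY <- stats::lm.fit(cbind(1, t(nIdx)), loci$y)
    p0 <- c(fitX$coefficients[1], fitY$coefficients[1])
    B <- rbind(fitX$coefficients[2:3], fitY$coefficients[2:3])
  }
  pred <- cbind(p0[1] + B[1, 1] * nIdx[1, ] + B[1, 2] * nIdx[2, ],
                p0[2] + B[2, 1] * nIdx[1, ] + B[2, 2] * nIdx[2, ])
  resid <- sqrt((loci$x - pred[, 1])^2 + (loci$y - pred[, 2])^2)

  n1 <- nIdx[1, ]; n2 <- nIdx[2, ]
  # canonical orientation: a2 advances down the image, a1 rightward
  if (B[2, 2] < 0) { n2 <- -n2; B[, 2] <- -B[, 2] }
  if (B[1, 1] < 0) { n1 <- -n1; B[, 1] <- -B[, 1] }

  keep <- resid <= tolerance
  loci <- loci[keep, , drop = FALSE]
  n1 <- n1[keep]; n2 <- n2[keep]; resid <- resid[keep]
  if (nrow(loci) == 0L) stop("no loci agree with the fitted lattice")

  # offset coordinates: row = n2, col = n1 + floor(row / 2), shifted to 0
  row <- as.integer(n2 - min(n2))
  colRaw <- n1 + floor(row / 2)
  col <- as.integer(colRaw - min(colRaw))

  loci$row <- row
  loci$col <- col
  loci$gridResidual <- resid

  # one locus per lattice node: highest confidence wins, ties by distance
  ord <- order(-loci$confidence, loci$gridResidual)
  loci <- loci[ord, , drop = FALSE]
  loci <- loci[!duplicated(paste(loci$row, loci$col)), , drop = FALSE]
  loci <- loci[order(loci$row, loci$col), , drop = FALSE]
  loci$wellId <- seq_len(nrow(loci)) - 1L
  rownames(loci) <- NULL
  loci
}

#' Run the full well-detection chain on one image
#'
#' Illumination flattening, lip binarization, dual-polarity circular Hough
#' detection, duplicate consolidation and hexagonal-grid filtering, with
#' defaults derived from the layout.
#'
#' @param image reference or first-timepoint sensor image (matrix).
#' @param layout an [ArrayLayout-class].
#' @param radii candidate Hough radii; default brackets the layout radius.
#' @param relThreshold,tolerance passed to [detectCircles()] /
#'   [enforceGrid()].
#' @return Grid-filtered locus table (see [enforceGrid()]).
#' @export
detectWells <- function(image, layout, radii = NULL, relThreshold = 0.5,
                        tolerance = NULL) {
  stopifnot(is(layout, "ArrayLayout"))
  r <- layout@wellRadiusPx
  if (is.null(radii))
    radii <- seq(max(2L, floor(0.6 * r)), ceiling(1.3 * r))
  corrected <- flattenIllumination(image, sigmaPx = max(24, 2 * layout@pitchPx))
  mask <- binarizeLips(corrected, layout)
  cand <- detectCircles(mask, radii, relThreshold = relThreshold)
  loci <- consolidateDetections(cand, minSeparation = layout@pitchPx / 2)
  loci <- refineCenters(corrected, loci, r)
  enforceGrid(loci, layout, tolerance = tolerance)
}

#' Refine circle centers by intensity-weighted centroids
#'
#' The bright lip annulus is symmetric about the true well center, so the
#' background-subtracted intensity centroid of the pixels around a candidate
#' center is a sub-pixel center estimate that tolerates partial lips and
#' binarization losses. Iterated a few times to escape the initial offset.
#'
#' @param image illumination-corrected image.
#' @param loci candidate loci (`x`, `y`).
#' @param radiusPx nominal well radius, pixels.
#' @param iterations centroid iterations.
#' @return `loci` with refined centers.
#' @export
refineCenters <- function(image, loci, radiusPx, iterations = 3L) {
  h <- nrow(image); w <- ncol(image)
  bg <- median(image)
  for (i in seq_len(nrow(loci))) {
    cx <- loci$x[i]; cy <- loci$y[i]
    for (it in seq_len(iterations)) {
      idx <- .diskIndices(cx, cy, 1.6 * radiusPx, h, w)
      if (length(idx) == 0L) break
      wgt <- pmax(image[idx] - bg, 0)
      s <- sum(wgt)
      if (s <= 0) break
      cy2 <- sum(((idx - 1L) %% h) * wgt) / s
      cx2 <- sum(((idx - 1L) %/% h) * wgt) / s
      moved <- abs(cx2 - cx) + abs(cy2 - cy)
      cx <- cx2; cy <- cy2
      if (moved < 1e-3) break
    }
    loci$x[i] <- cx; loci$y[i] <- cy
  }
  loci
}

#' Track rigid array motion over a time-lapse stack
#'
#' Re-detects wells inside a cropped sub-region of every frame and matches
#' them to the frame-0 loci by mutual nearest neighbours; the per-frame
#' rigid translation is the mean matched displacement. Cropping exploits the
#' rigidity of the array to cut processing cost. Frame 1 is the reference
#' and carries translation (0, 0) by definition.
#'
#' @param refLoci frame-0 locus table (from [detectWells()]).
#' @param stack numeric array `[h, w, frames]` (any channel showing lips).
#' @param layout an [ArrayLayout-class].
#' @param crop `c(x0, y0, width, height)` in 0-based pixels; default a
#'   centered square of 6 pitches. Must contain at least 9 wells.
#' @param maxShift largest expected per-frame shift, pixels.
#' @return data.frame (`frame`, `dx`, `dy`) of cumulative translations.
#' @export
trackArray <- function(refLoci, stack, layout, crop = NULL, maxShift = NULL) {
  h <- dim(stack)[1]; w <- dim(stack)[2]; nT <- dim(stack)[3]
  pitch <- layout@pitchPx
  if (is.null(maxShift)) maxShift <- pitch / 2.5
  if (is.null(crop)) {
    side <- min(6 * pitch, w - 2, h - 2)
    crop <- c(floor((w - side) / 2), floor((h - side) / 2), side, side)
  }
  inCrop <- refLoci$x >= crop[1] + pitch / 2 &
    refLoci$x <= crop[1] + crop[3] - pitch / 2 &
    refLoci$y >= crop[2] + pitch / 2 &
    refLoci$y <= crop[2] + crop[4] - pitch / 2
  ref <- refLoci[inCrop, , drop = FALSE]
  if (nrow(ref) < 9L)
    stop("crop contains fewer than 9 reference wells; enlarge the crop")

  rows <- (crop[2] + 1):(crop[2] + crop[4])
  cols <- (crop[1] + 1):(crop[1] + crop[3])
  radii <- seq(max(2L, floor(0.7 * layout@wellRadiusPx)),
               ceiling(1.25 * layout@wellRadiusPx))
  out <- data.frame(frame = seq_len(nT), dx = 0, dy = 0)
  prev <- c(0, 0)
  for (t in 2:nT) {
    sub <- stack[rows, cols, t]
    corrected <- tryCatch(flattenIllumination(sub, sigmaPx = 2 * pitch),
                          error = function(e) NULL)
    if (is.null(corrected))
      stop(sprintf("tracking lost all wells in frame %d (degenerate crop)", t))
    lipFrac <- nrow(ref) * pi * layout@wellRadiusPx^2 * (1.15^2 - 0.88^2) /
      length(sub)
    thr <- quantile(corrected, 1 - min(max(lipFrac, 1e-4), 0.5), names = FALSE)
    mask <- corrected > thr
    cand <- detectCircles(mask, radii)
    det <- consolidateDetections(cand, minSeparation = pitch / 2)
    if (nrow(det) == 0L)
      stop(sprintf("tracking lost all wells in frame %d", t))
    det$x <- det$x + crop[1]
    det$y <- det$y + crop[2]
    # mutual nearest-neighbour matching after applying the previous shift
    px <- ref$x + prev[1]; py <- ref$y + prev[2]
    dmat <- outer(px, det$x, "-")^2 + outer(py, det$y, "-")^2
    fwd <- apply(dmat, 1, which.min)
    bwd <- apply(dmat, 2, which.min)
    mutual <- which(bwd[fwd] == seq_along(fwd) &
                      dmat[cbind(seq_along(fwd), fwd)] <= maxShift^2)
    if (length(mutual) == 0L)
      stop(sprintf("tracking lost all wells in frame %d", t))
    dx <- mean(det$x[fwd[mutual]] - ref$x[mutual])
    dy <- mean(det$y[fwd[mutual]] - ref$y[mutual])
    out$dx[t] <- dx
    out$dy[t] <- dy
    prev <- c(dx, dy)
  }
  out
}

#' Fit a non-reflective similarity transform between point sets
#'
#' Closed-form least-squares estimate of scale, rotation and translation
#' mapping `pointsA` onto `pointsB`, with the rotation constrained to a
#' positive determinant (orientation-preserving), as used to carry assay
#' well coordinates into the higher-magnification cell-count images.
#'
#' @param pointsA,pointsB n x 2 matrices of corresponding points (n >= 2).
#' @return A [SimilarityTransform-class] with the fit RMS residual.
#' @export
fitSimilarityTransform <- function(pointsA, pointsB) {
  A <- as.matrix(pointsA); B <- as.matrix(pointsB)
  stopifnot(ncol(A) == 2L, ncol(B) == 2L, nrow(A) == nrow(B))
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 corresponding point pairs")
  muA <- colMeans(A); muB <- colMeans(B)
  Ac <- sweep(A, 2, muA); Bc <- sweep(B, 2, muB)
  varA <- sum(Ac^2) / n
  if (varA == 0) stop("all source points coincident: transform is undefined")
  H <- crossprod(Ac, Bc) / n
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  S <- diag(c(1, d))
  Rm <- sv$v %*% S %*% t(sv$u)
  scale <- sum(diag(diag(sv$d) %*% S)) / varA
  trans <- muB - scale * as.numeric(Rm %*% muA)
  pred <- t(scale * Rm %*% t(A) + trans)
  rms <- sqrt(mean(rowSums((B - pred)^2)))
  new("SimilarityTransform", scale = scale,
      rotation = atan2(Rm[2, 1], Rm[1, 1]), translation = trans, rms = rms)
}

#' Apply a similarity transform to points
#'
#' @param transform a [SimilarityTransform-class].
#' @param points n x 2 matrix (or data.frame with `x`, `y`).
#' @return n x 2 matrix of transformed points.
#' @export
applyTransform <- function(transform, points) {
  stopifnot(is(transform, "SimilarityTransform"))
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  th <- transform@rotation
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t(transform@scale * Rm %*% t(points) + transform@translation)
}
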