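# Well quality control: internal-reference inspection of segmented wells and
# seal-integrity classification from the terminal oxygen-purge phase.

#' Segment square crops around each well
#'
#' @param image 2-D matrix.
#' @param loci well table with `x`, `y` centers (0-based pixels).
#' @param halfSize crop half-width in pixels; crops are
#'   `(2 halfSize + 1)^2`. Wells whose crop leaves the image get `NA` slabs.
#' @return Array `[2h+1, 2h+1, nWells]` of crops.
#' @export
segmentWells <- function(image, loci, halfSize) {
  h <- nrow(image); w <- ncol(image)
  side <- 2L * halfSize + 1L
  out <- array(NA_real_, c(side, side, nrow(loci)))
  for (i in seq_len(nrow(loci))) {
    cx <- as.integer(round(loci$x[i])); cy <- as.integer(round(loci$y[i]))
    if (cx - halfSize < 0 || cx + halfSize > w - 1 ||
        cy - halfSize < 0 || cy + halfSize > h - 1) next
    out[, , i] <- image[(cy - halfSize):(cy + halfSize) + 1L,
                        (cx - halfSize):(cx + halfSize) + 1L]
  }
  out
}

#' Build the internal reference well image
#'
#' The pixel-wise mean of all segmented well images, scaled to an overall
#' mean of one. Assumes most wells are valid, so the mean is the archetype
#' against which individual wells are inspected.
#'
#' @param segments array `[h, w, nWells]` from [segmentWells()] (>= 10 valid
#'   wells required).
#' @return Matrix of the same crop size with mean exactly 1.
#' @export
buildReferenceWell <- function(segments) {
  if (is.list(segments)) {
    dims <- unique(lapply(segments, dim))
    if (length(dims) != 1L) stop("mismatched segment shapes")
    segments <- simplify2array(segments)
  }
  stopifnot(length(dim(segments)) == 3L)
  valid <- apply(segments, 3, function(s) !any(is.na(s)))
  if (sum(valid) < 10L) stop("need at least 10 valid well segments")
  ref <- apply(segments[, , valid, drop = FALSE], c(1, 2), mean)
  ref / mean(ref)
}

#' Inspect wells against the internal reference
#'
#' Each segment is divided by the reference image and mean-normalized to one
#' (removing bulk-intensity differences caused by sensor-film
#' heterogeneity); a perfect well then holds 1 everywhere. The pixel
#' coefficient of variation (%) of the ratio image quantifies data
#' integrity; wells above the cutoff are flagged. Zero (or negative)
#' reference pixels are excluded from the CV rather than divided.
#'
#' @param segments array `[h, w, nWells]`.
#' @param reference matrix from [buildReferenceWell()].
#' @param cutoff CV cutoff in percent; `NULL` selects the robust default
#'   `median(CV) + 5 * MAD(CV)` across wells.
#' @param smoothSigma light Gaussian pre-smoothing (pixels) applied to
#'   segments and reference alike before the ratio; suppresses the spurious
#'   CV contribution of sub-pixel crop misalignment at the steep lip edge
#'   while leaving area defects visible. 0 disables.
#' @return data.frame (`wellId` row order as segments, `cvPercent`,
#'   `status` in `pass` / `defect_fail`), with the applied cutoff as an
#'   attribute.
#' @export
inspectWells <- function(segments, reference, cutoff = NULL,
                         smoothSigma = 1) {
  stopifnot(length(dim(segments)) == 3L,
            all(dim(segments)[1:2] == dim(reference)))
  blur <- function(m) {
    if (smoothSigma <= 0) return(m)
    as.matrix(EBImage::gblur(m, sigma = smoothSigma, boundary = "replicate"))
  }
  reference <- blur(reference)
  ok <- reference > 0
  nwound <- dim(segments)[3]
  cv <- rep(NA_real_, nwound)
  for (i in seq_len(nwound)) {
    s <- segments[, , i]
    if (any(is.na(s))) next
    s <- blur(s)
    ratio <- s[ok] / reference[ok]
    m <- mean(ratio)
    if (m <= 0) { cv[i] <- Inf; next }
    ratio <- ratio / m
    cv[i] <- sd(ratio) * 100
  }
  if (is.null(cutoff)) {
    fin <- cv[is.finite(cv)]
    cutoff <- median(fin) + 5 * mad(fin)
  }
  status <- ifelse(is.na(cv), "defect_fail",
                   ifelse(cv <= cutoff, "pass", "defect_fail"))
  out <- data.frame(wellId = seq_len(nwound) - 1L, cvPercent = cv,
                    status = status)
  attr(out, "cutoff") <- cutoff
  out
}

#' Classify seal integrity from the oxygen-purge phase
#'
#' During the terminal seal test, oxygen flooding the fixture quenches the
#' sensor; sealed wells hold their intensity, while partially sealed wells
#' show a decreasing trend. Per well, the linear slope over the purge frames
#' is tested one-sided against the pre-purge noise scale: a well is leaky
#' when its slope is significantly negative at level `alpha`. The purge
#' itself is confirmed globally from the drop of the outside-region trace;
#' without that confirmation all seal calls are marked unreliable.
#'
#' @param o2Center matrix `[wells, frames]` of oxygen-channel center means.
#' @param times frame timestamps, minutes.
#' @param purgeStart 1-based index of the first purge frame (>= 5 purge
#'   frames required).
#' @param outsideTrace mean outside-region oxygen trace (length frames) used
#'   for global purge confirmation; `NULL` skips the check (treated as
#'   confirmed).
#' @param alpha one-sided significance level for the leak call.
#' @param noiseScale per-frame intensity noise SD; `NULL` estimates it from
#'   pre-purge first differences per well.
#' @return data.frame (`wellId`, `sealed`, `purgeSlope`, `zStat`) with
#'   attributes `purgeConfirmed` and `reliable`.
#' @export
classifySeal <- function(o2Center, times, purgeStart, outsideTrace = NULL,
                         alpha = 0.01, noiseScale = NULL) {
  if (is.null(dim(o2Center))) o2Center <- matrix(o2Center, nrow = 1)
  nT <- ncol(o2Center)
  stopifnot(length(times) == nT, !is.na(purgeStart))
  nPurge <- nT - purgeStart + 1L
  if (nPurge < 5L) stop("need at least 5 purge frames for the seal test")
  tp <- times[purgeStart:nT]
  sxx <- sum((tp - mean(tp))^2)
  nw <- nrow(o2Center)

  purgeConfirmed <- TRUE
  if (!is.null(outsideTrace)) {
    pre <- mean(outsideTrace[seq_len(purgeStart - 1L)], na.rm = TRUE)
    dur <- mean(outsideTrace[purgeStart:nT], na.rm = TRUE)
    purgeConfirmed <- is.finite(pre) && is.finite(dur) && dur < 0.8 * pre
  }

  sealed <- rep(NA, nw)
  slope <- rep(NA_real_, nw)
  zstat <- rep(NA_real_, nw)
  for (i in seq_len(nw)) {
    y <- o2Center[i, purgeStart:nT]
    if (any(is.na(y))) next
    fit <- .olsLine(tp, y)
    # noise floor: per-frame scatter of the pre-purge trace (first
    # differences are sqrt(2) noisier than the points themselves)
    sig <- noiseScale
    if (is.null(sig)) {
      pre <- o2Center[i, seq_len(purgeStart - 1L)]
      sig <- mad(diff(pre), na.rm = TRUE) / sqrt(2)
    }
    sig <- max(sig, fit$rmse, 1e-12 * max(abs(y), 1))
    se <- sig / sqrt(sxx)
    zstat[i] <- fit$slope / se
    slope[i] <- fit$slope
    sealed[i] <- zstat[i] > qnorm(alpha)   # not significantly negative
  }
  out <- data.frame(wellId = seq_len(nw) - 1L, sealed = sealed,
                    purgeSlope = slope, zStat = zstat)
  attr(out, "purgeConfirmed") <- purgeConfirmed
  attr(out, "reliable") <- purgeConfirmed
  out
}
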