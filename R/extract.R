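# Region-trace extraction: per-well, per-channel, per-region intensity means
# and standard deviations over time, plus ratiometric normalization.

#' Concentric extraction regions for a given well radius
#'
#' Defaults relative to the detected well radius r: center disk 0.75 r, lip
#' annulus (0.9 r, 1.15 r], outside annulus (1.25 r, 1.5 r]. The center
#' region monitors the cell; lip and outside serve as references for the
#' surrounding environment.
#'
#' @param wellRadiusPx detected well radius, pixels.
#' @param center,lipIn,lipOut,outIn,outOut radii as fractions of
#'   `wellRadiusPx`.
#' @return A [RegionSpec-class].
#' @export
regionSpec <- function(wellRadiusPx, center = 0.75, lipIn = 0.9,
                       lipOut = 1.15, outIn = 1.25, outOut = 1.5) {
  new("RegionSpec",
      centerRadius = center * wellRadiusPx,
      lipInner = lipIn * wellRadiusPx, lipOuter = lipOut * wellRadiusPx,
      outsideInner = outIn * wellRadiusPx, outsideOuter = outOut * wellRadiusPx)
}

#' Extract per-well region traces from image stacks
#'
#' For every well, channel and frame, computes the mean and standard
#' deviation of the pixels whose centers fall within the three concentric
#' regions of `spec`, after applying the rigid track correction. Wells whose
#' outermost region leaves the image in any frame are flagged out-of-bounds
#' (their traces are set to `NA`), never silently dropped.
#'
#' @param stacks named list of `[h, w, frames]` arrays; names become the
#'   channel dimension (canonically `o2`, `ph`, `ref`).
#' @param loci well table with `x`, `y` (frame-0 centers, 0-based pixels).
#' @param spec a [RegionSpec-class].
#' @param times frame timestamps, minutes.
#' @param track optional rigid track (`frame`, `dx`, `dy`) from
#'   [trackArray()]; `NULL` means a static array.
#' @param purgeStart 1-based index of the first purge frame (`NA` if none).
#' @return A [WellTraces-class]; the `wells` slot carries `inBounds` flags.
#' @export
extractRegionTraces <- function(stacks, loci, spec, times, track = NULL,
                                purgeStart = NA_integer_) {
  stopifnot(is.list(stacks), length(stacks) >= 1L, is(spec, "RegionSpec"))
  dims <- dim(stacks[[1]])
  h <- dims[1]; w <- dims[2]; nT <- dims[3]
  stopifnot(length(times) == nT)
  channels <- names(stacks)
  regions <- c("center", "lip", "outside")
  nw <- nrow(loci)
  if (is.null(track)) track <- data.frame(frame = seq_len(nT), dx = 0, dy = 0)

  inBounds <- rep(TRUE, nw)
  rng <- range(track$dx)
  rngY <- range(track$dy)
  rOut <- spec@outsideOuter
  inBounds <- loci$x + min(rng) - rOut >= 0 & loci$x + max(rng) + rOut <= w - 1 &
    loci$y + min(rngY) - rOut >= 0 & loci$y + max(rngY) + rOut <= h - 1

  means <- array(NA_real_, c(nw, length(channels), 3L, nT),
                 dimnames = list(NULL, channels, regions, NULL))
  sds <- array(NA_real_, c(nw, length(channels), 3L, nT),
               dimnames = list(NULL, channels, regions, NULL))

  static <- all(track$dx == 0) && all(track$dy == 0)
  wellIdx <- which(inBounds)

  buildIndex <- function(dx, dy) {
    idxList <- vector("list", 3L * length(wellIdx))
    grpList <- vector("list", 3L * length(wellIdx))
    pos <- 0L
    for (wi in seq_along(wellIdx)) {
      i <- wellIdx[wi]
      cx <- loci$x[i] + dx; cy <- loci$y[i] + dy
      regs <- list(
        .diskIndices(cx, cy, spec@centerRadius, h, w),
        .annulusIndices(cx, cy, spec@lipInner, spec@lipOuter, h, w),
        .annulusIndices(cx, cy, spec@outsideInner, spec@outsideOuter, h, w)
      )
      for (rix in 1:3) {
        pos <- pos + 1L
        idxList[[pos]] <- regs[[rix]]
        grpList[[pos]] <- rep.int((wi - 1L) * 3L + rix, length(regs[[rix]]))
      }
    }
    list(idx = unlist(idxList), grp = unlist(grpList),
         counts = as.numeric(table(factor(unlist(grpList),
                                          levels = seq_len(3L * length(wellIdx))))))
  }

  ix <- if (static) buildIndex(0, 0) else NULL
  for (t in seq_len(nT)) {
    if (!static) ix <- buildIndex(track$dx[t], track$dy[t])
    grpF <- factor(ix$grp, levels = seq_len(3L * length(wellIdx)))
    for (ch in seq_along(channels)) {
      v <- stacks[[ch]][, , t][ix$idx]
      s1 <- as.numeric(rowsum(v, grpF))
      s2 <- as.numeric(rowsum(v * v, grpF))
      mu <- s1 / ix$counts
      varv <- pmax(0, (s2 - ix$counts * mu^2) / pmax(ix$counts - 1, 1))
      for (rix in 1:3) {
        sel <- seq(rix, by = 3L, length.out = length(wellIdx))
        means[wellIdx, ch, rix, t] <- mu[sel]
        sds[wellIdx, ch, rix, t] <- sqrt(varv[sel])
      }
    }
  }

  wells <- loci
  wells$inBounds <- inBounds
  new("WellTraces", means = means, sds = sds, times = times,
      purgeStart = as.integer(purgeStart), wells = wells)
}

#' Ratiometric normalization against the reference channel
#'
#' Divides each sensor channel's center trace frame-wise by the
#' reference-channel center trace of the same well, then rescales so that
#' frame 0 equals the raw frame-0 sensor mean. Common-mode gain drift (film
#' thickness, illumination, focus) cancels while the intensity units are
#' preserved. Wells with a non-positive reference mean at any frame are
#' flagged (`refValid = FALSE`) and left unnormalized.
#'
#' @param traces a [WellTraces-class] containing a `ref` channel.
#' @return A [WellTraces-class] with normalized `o2` and `ph` center traces
#'   and a `refValid` column in the well table.
#' @export
normalizeRatiometric <- function(traces) {
  stopifnot(is(traces, "WellTraces"))
  channels <- dimnames(traces@means)[[2]]
  if (!"ref" %in% channels) stop("traces lack a reference channel")
  ref <- traces@means[, "ref", "center", , drop = TRUE]
  if (is.null(dim(ref))) ref <- matrix(ref, nrow = 1)
  bad <- apply(ref <= 0 | is.na(ref), 1, any)
  out <- traces
  for (ch in setdiff(channels, "ref")) {
    raw <- traces@means[, ch, "center", , drop = TRUE]
    if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
    ratio <- raw / ref
    scaled <- ratio / ratio[, 1] * raw[, 1]
    scaled[bad, ] <- raw[bad, ]
    out@means[, ch, "center", ] <- scaled
  }
  out@wells$refValid <- !bad
  out
}
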