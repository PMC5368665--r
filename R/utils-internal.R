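# Internal geometry / image helpers shared across modules.
#
# Pixel convention used everywhere: pixel centers sit at integer coordinates,
# origin top-left, x rightward, y downward, 0-based. A matrix element
# m[row, col] is the pixel at x = col - 1, y = row - 1.

# Linear (column-major) indices of pixels whose centers fall inside the disk
# of radius r around (cx, cy). Returns integer(0) when the disk misses the
# image entirely.
.diskIndices <- function(cx, cy, r, h, w) {
  x0 <- max(0L, as.integer(ceiling(cx - r)))
  x1 <- min(w - 1L, as.integer(floor(cx + r)))
  y0 <- max(0L, as.integer(ceiling(cy - r)))
  y1 <- min(h - 1L, as.integer(floor(cy + r)))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1
  ys <- y0:y1
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  keep <- (gx - cx)^2 + (gy - cy)^2 <= r^2
  (gy[keep] + 1L) + gx[keep] * h
}

# Annulus with rin < d <= rout (pixel-center test); rin = 0 gives a punctured
# disk, use .diskIndices for a full disk.
.annulusIndices <- function(cx, cy, rin, rout, h, w) {
  x0 <- max(0L, as.integer(ceiling(cx - rout)))
  x1 <- min(w - 1L, as.integer(floor(cx + rout)))
  y0 <- max(0L, as.integer(ceiling(cy - rout)))
  y1 <- min(h - 1L, as.integer(floor(cy + rout)))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1
  ys <- y0:y1
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  d2 <- (gx - cx)^2 + (gy - cy)^2
  keep <- d2 > rin^2 & d2 <= rout^2
  (gy[keep] + 1L) + gx[keep] * h
}

# Centers of a hexagonally packed grid: odd rows are offset by half a pitch,
# row spacing is pitch * sqrt(3) / 2.
.hexCenters <- function(rows, cols, pitch, margin) {
  r <- rep(seq_len(rows) - 1L, each = cols)
  c <- rep(seq_len(cols) - 1L, times = rows)
  data.frame(
    row = r, col = c,
    x = margin + (c + 0.5 * (r %% 2L)) * pitch,
    y = margin + r * pitch * sqrt(3) / 2
  )
}

# Rigid integer shift of a matrix, vacated pixels filled with `fill`.
.shiftMatrix <- function(m, dx, dy, fill = 0) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  if (dx == 0L && dy == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  sr <- max(1L, 1L + dy):min(h, h + dy)
  sc <- max(1L, 1L + dx):min(w, w + dx)
  if (length(sr) > 0L && length(sc) > 0L)
    out[sr, sc] <- m[sr - dy, sc - dx]
  out
}

# 2-D linear cross-correlation with zero padding outside the image,
# via EBImage's FFT filter. Kernel dimensions are forced odd.
.xcorr2 <- function(img, kernel) {
  if (nrow(kernel) %% 2L == 0L) kernel <- rbind(kernel, 0)
  if (ncol(kernel) %% 2L == 0L) kernel <- cbind(kernel, 0)
  as.matrix(EBImage::filter2(img, kernel, boundary = 0))
}

# One-pixel-thick ring kernel of radius r (pixels with |d - r| <= 0.5).
.ringKernel <- function(r) {
  k <- as.integer(ceiling(r + 1))
  ax <- (-k):k
  d <- sqrt(outer(ax^2, ax^2, "+"))
  out <- matrix(0, 2L * k + 1L, 2L * k + 1L)
  out[abs(d - r) <= 0.5] <- 1
  out
}

# Scale-normalized Laplacian-of-Gaussian kernel; convolving a bright blob of
# scale sigma with -LoG yields a positive peak at its center.
.logKernel <- function(sigma) {
  k <- as.integer(ceiling(3 * sigma))
  ax <- (-k):k
  x2 <- outer(ax^2, rep(1, length(ax)))
  y2 <- t(x2)
  r2 <- x2 + y2
  g <- exp(-r2 / (2 * sigma^2))
  log_k <- (r2 - 2 * sigma^2) / sigma^2 * g
  log_k - mean(log_k)  # zero-mean so flat regions give zero response
}

# Strict-ish local maxima: value >= all 8 neighbours and above `thr`.
# Returns a data.frame of 0-based x/y and the value.
.localMaxima <- function(m, thr) {
  h <- nrow(m); w <- ncol(m)
  ok <- m > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L) next
    ok <- ok & m >= .shiftMatrix(m, dx, dy, fill = -Inf)
  }
  idx <- which(ok)
  if (length(idx) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  data.frame(
    x = ((idx - 1L) %/% h),
    y = ((idx - 1L) %% h),
    value = m[idx]
  )
}

# Connected components of the graph linking points closer than `cutoff`
# (equivalent to single-linkage clustering cut at `cutoff`). Grid-bucketed so
# it scales to tens of thousands of points.
.linkComponents <- function(x, y, cutoff) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cx <- floor(x / cutoff)
  cy <- floor(y / cutoff)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  lookup <- buckets
  for (i in seq_len(n)) {
    for (ddx in -1:1) for (ddy in -1:1) {
      k <- paste(cx[i] + ddx, cy[i] + ddy)
      js <- lookup[[k]]
      if (is.null(js)) next
      js <- js[js > i]
      if (length(js) == 0L) next
      d2 <- (x[js] - x[i])^2 + (y[js] - y[i])^2
      for (j in js[d2 < cutoff^2]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Nearest neighbour (excluding self) within maxDist, grid-bucketed.
# Returns list(idx, dist) with NA where no neighbour exists.
.nearestNeighbor <- function(x, y, maxDist) {
  n <- length(x)
  nnIdx <- rep(NA_integer_, n)
  nnDist <- rep(NA_real_, n)
  if (n < 2L) return(list(idx = nnIdx, dist = nnDist))
  cx <- floor(x / maxDist)
  cy <- floor(y / maxDist)
  key <- paste(cx, cy)
  lookup <- split(seq_len(n), key)
  for (i in seq_len(n)) {
    best <- NA_integer_; bestD2 <- maxDist^2
    for (ddx in -1:1) for (ddy in -1:1) {
      js <- lookup[[paste(cx[i] + ddx, cy[i] + ddy)]]
      if (is.null(js)) next
      for (j in js) {
        if (j == i) next
        d2 <- (x[j] - x[i])^2 + (y[j] - y[i])^2
        if (d2 <= bestD2) { bestD2 <- d2; best <- j }
      }
    }
    if (!is.na(best)) { nnIdx[i] <- best; nnDist[i] <- sqrt(bestD2) }
  }
  list(idx = nnIdx, dist = nnDist)
}

# Ordinary least squares of y on t returning slope, intercept, se(slope),
# rmse and r-squared; the workhorse behind rate estimation.
.olsLine <- function(t, y) {
  n <- length(t)
  stopifnot(n >= 2L, length(y) == n)
  mt <- mean(t); my <- mean(y)
  sxx <- sum((t - mt)^2)
  if (sxx == 0) stop("degenerate time axis: all timestamps identical")
  slope <- sum((t - mt) * (y - my)) / sxx
  intercept <- my - slope * mt
  resid <- y - (intercept + slope * t)
  rss <- sum(resid^2)
  df <- n - 2L
  sigma2 <- if (df > 0L) rss / df else 0
  tss <- sum((y - my)^2)
  list(
    slope = slope, intercept = intercept,
    se = sqrt(sigma2 / sxx),
    rmse = sqrt(rss / n),
    r2 = if (tss > 0) 1 - rss / tss else 1,
    df = df
  )
}
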