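#' Otsu threshold of an intensity sample
#'
#' Picks the cut that maximizes the between-class variance of the sample's
#' histogram. Integer-valued samples are histogrammed at unit resolution so
#' the result is shift-equivariant (threshold(x + c) = threshold(x) + c);
#' continuous samples use \code{n_bins} equal-width bins. Ties over equally
#' good cuts are resolved by averaging, the usual Otsu convention.
#'
#' @param values numeric vector of intensities (at least two distinct values).
#' @param n_bins number of histogram bins for non-integer data.
#' @return scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- values[is.finite(values)]
  if (length(v) < 2L || length(unique(v)) < 2L)
    stopf("otsu_threshold: degenerate input (fewer than 2 distinct values)")
  int_mode <- all(abs(v - round(v)) < 1e-9) && diff(range(v)) <= 65535
  if (int_mode) {
    lo <- min(v)
    counts <- tabulate(as.integer(round(v - lo)) + 1L,
                       nbins = as.integer(diff(range(v))) + 1L)
    mids <- seq(lo, max(v))
    cuts <- mids + 0.5          # cut after each level
  } else {
    br <- seq(min(v), max(v), length.out = n_bins + 1L)
    h <- graphics::hist(v, breaks = br, plot = FALSE)
    counts <- h$counts
    mids <- h$mids
    cuts <- br[-1L]
  }
  p <- counts / sum(counts)
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  k <- seq_len(length(p) - 1L)   # cut after bin k
  denom <- w[k] * (1 - w[k])
  sigma_b <- ifelse(denom > 0, (mu_t * w[k] - mu[k])^2 / denom, -Inf)
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  mean(cuts[best])
}

#' Two-threshold (three-class) Otsu cuts
#'
#' Exhaustive search for the pair of cuts maximizing the between-class
#' variance of a three-class split. Used where an image carries three
#' populations (glass background, unstained tissue, stained signal) and the
#' lower cut is the boundary of interest.
#'
#' @param values numeric vector with at least three distinct values.
#' @param n_bins histogram resolution.
#' @return numeric length-2 vector of increasing thresholds.
#' @export
otsu_thresholds2 <- function(values, n_bins = 128L) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 3L)
    stopf("otsu_thresholds2: need at least 3 distinct values")
  br <- seq(min(v), max(v), length.out = n_bins + 1L)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  W <- cumsum(p); M <- cumsum(p * mids)
  nb <- length(p)
  best <- c(-Inf, 1L, 2L)
  for (i in 1L:(nb - 2L)) {
    w0 <- W[i]; m0 <- M[i]
    if (w0 <= 0) next
    j <- (i + 1L):(nb - 1L)
    w1 <- W[j] - w0; m1 <- M[j] - m0
    w2 <- 1 - W[j]; m2 <- M[nb] - M[j]
    ok <- w1 > 0 & w2 > 0
    sb <- rep(-Inf, length(j))
    sb[ok] <- (m0^2 / w0 + m1[ok]^2 / w1[ok] + m2[ok]^2 / w2[ok])
    k <- which.max(sb)
    if (sb[k] > best[1]) best <- c(sb[k], i, j[k])
  }
  c(br[best[2] + 1L], br[best[3] + 1L])
}

## Bilinear interpolation of a coarse grid of block thresholds onto the
## full pixel raster (rule = 2 clamps beyond the outermost block centers).
interp_block_grid <- function(grid, centers_y, centers_x, ny, nx) {
  if (length(centers_y) == 1L) {
    rows <- matrix(grid[1L, ], nrow = ny, ncol = length(centers_x), byrow = TRUE)
  } else {
    rows <- vapply(seq_along(centers_x), function(j)
      stats::approx(centers_y, grid[, j], xout = seq_len(ny), rule = 2)$y,
      numeric(ny))
  }
  if (length(centers_x) == 1L) {
    return(matrix(rows[, 1L], nrow = ny, ncol = nx))
  }
  out <- matrix(0, ny, nx)
  xs <- seq_len(nx)
  for (i in seq_len(ny)) {
    out[i, ] <- stats::approx(centers_x, rows[i, ], xout = xs, rule = 2)$y
  }
  out
}

#' Adaptive (block-wise) Otsu mask
#'
#' Computes Otsu thresholds in square blocks, interpolates them bilinearly
#' between block centers, and thresholds the image against the resulting
#' map. Blocks whose intensity range is too narrow to be bimodal (less than
#' half the global range within the region of interest), or that contain too
#' few region pixels, fall back to the global Otsu threshold.
#'
#' @param img numeric matrix of intensities.
#' @param roi optional logical matrix restricting both threshold estimation
#'   and the output mask.
#' @param block_px block edge length in pixels (minimum 32).
#' @param min_block_n minimum number of in-region pixels for a block to get
#'   its own threshold.
#' @return logical mask (TRUE = above threshold, inside \code{roi}); the
#'   global threshold is attached as attribute \code{"global_threshold"}.
#' @export
adaptive_otsu_mask <- function(img, roi = NULL, block_px = 128L,
                               min_block_n = 200L) {
  if (block_px < 32L) stopf("adaptive_otsu_mask: block_px must be >= 32")
  ny <- nrow(img); nx <- ncol(img)
  if (is.null(roi)) roi <- matrix(TRUE, ny, nx)
  vals <- img[roi]
  if (length(vals) == 0L) stopf("adaptive_otsu_mask: empty region of interest")
  if (length(unique(vals)) < 2L)
    stopf("adaptive_otsu_mask: region of interest is constant")
  thr_g <- otsu_threshold(vals)
  rng_g <- diff(range(vals))

  nby <- max(1L, floor(ny / block_px))
  nbx <- max(1L, floor(nx / block_px))
  ybr <- round(seq(0L, ny, length.out = nby + 1L))
  xbr <- round(seq(0L, nx, length.out = nbx + 1L))
  grid <- matrix(thr_g, nby, nbx)
  cy <- (ybr[-1L] + ybr[-(nby + 1L)] + 1) / 2
  cx <- (xbr[-1L] + xbr[-(nbx + 1L)] + 1) / 2
  for (bi in seq_len(nby)) {
    for (bj in seq_len(nbx)) {
      ys <- (ybr[bi] + 1L):ybr[bi + 1L]
      xs <- (xbr[bj] + 1L):xbr[bj + 1L]
      sel <- roi[ys, xs]
      bv <- img[ys, xs][sel]
      if (length(bv) >= min_block_n && length(unique(bv)) >= 2L &&
          diff(range(bv)) >= 0.5 * rng_g) {
        grid[bi, bj] <- otsu_threshold(bv)
      }
    }
  }
  thr_map <- interp_block_grid(grid, cy, cx, ny, nx)
  mask <- (img > thr_map) & roi
  attr(mask, "global_threshold") <- thr_g
  mask
}
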