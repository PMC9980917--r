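#' @importFrom stats rnorm runif rlnorm rexp rbinom quantile median sd var cor
#' @importFrom stats fft pnorm qnorm plogis qlogis t.test wilcox.test cor.test
#' @importFrom stats fisher.test chisq.test p.adjust setNames complete.cases
#' @importFrom utils write.csv read.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a private, restored RNG state
#'
#' All stochastic operations in the package take an explicit seed and run
#' through this helper, so no call touches the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_rng <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prop <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("%s must be a proportion in [0, 1]", name)
  invisible(x)
}

## EBImage returns Image objects; keep plain matrices throughout.
as_mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

mat_gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as_mat(EBImage::gblur(m, sigma = sigma))
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

mat_erode <- function(m, radius = 1) {
  as_mat(EBImage::erode(m * 1, disc_brush(radius))) > 0.5
}

mat_dilate <- function(m, radius = 1) {
  as_mat(EBImage::dilate(m * 1, disc_brush(radius))) > 0.5
}

mat_fill_holes <- function(m) {
  as_mat(EBImage::fillHull(m * 1)) > 0.5
}

mat_label <- function(m) {
  as_mat(EBImage::bwlabel(m * 1))
}

clip01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

#' Translate a matrix by an integer pixel offset
#'
#' Shifts content by \code{dx} columns and \code{dy} rows (positive = towards
#' larger indices); vacated pixels are filled with \code{fill}.
#'
#' @param m numeric matrix.
#' @param dx,dy integer offsets in pixels (columns, rows).
#' @param fill fill value for out-of-view pixels.
#' @return matrix of the same dimension.
#' @export
translate_mat <- function(m, dx, dy, fill = 0) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}
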