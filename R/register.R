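#' Estimate the round-2 to round-1 translation from the shared DAPI channel
#'
#' Translation-only registration by spectral cross-correlation: the shift
#' maximizing the circular cross-correlation of the mean-subtracted DAPI
#' images is located on the FFT grid and refined to subpixel precision with a
#' separable three-point parabolic fit. The registration score is the Pearson
#' correlation of the two images over their overlap at the integer shift;
#' registration is flagged as failed when it falls below \code{min_score}.
#'
#' @param dapi_r1,dapi_r2 numeric matrices of equal dimension (round-1 and
#'   round-2 DAPI).
#' @param min_score minimum acceptable overlap correlation (default 0.5).
#' @return list of class \code{registration_result}: \code{shift} (dx, dy; the
#'   translation taking round 1 into round 2), \code{shift_int}, \code{score}
#'   and \code{ok}.
#' @export
estimate_shift <- function(dapi_r1, dapi_r2, min_score = 0.5) {
  if (!all(dim(dapi_r1) == dim(dapi_r2)))
    stopf("estimate_shift: images must have identical dimensions")
  if (sd(dapi_r1) == 0 || sd(dapi_r2) == 0)
    stopf("estimate_shift: degenerate (constant) input image")
  a <- dapi_r1 - mean(dapi_r1)
  b <- dapi_r2 - mean(dapi_r2)
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / length(a)

  nr <- nrow(cc); nc <- ncol(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dy_i <- unname(wrap(pk[1], nr))
  dx_i <- unname(wrap(pk[2], nc))

  # parabolic subpixel refinement on circularly-indexed neighbours
  cyc <- function(i, n) ((i - 1) %% n) + 1
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (abs(den) < 1e-12) 0 else 0.5 * (cm - cp) / den
  }
  ddy <- para(cc[cyc(pk[1] - 1, nr), pk[2]], cc[pk[1], pk[2]],
              cc[cyc(pk[1] + 1, nr), pk[2]])
  ddx <- para(cc[pk[1], cyc(pk[2] - 1, nc)], cc[pk[1], pk[2]],
              cc[pk[1], cyc(pk[2] + 1, nc)])

  # score: correlation over the valid overlap at the integer shift
  b_back <- translate_mat(dapi_r2, -dx_i, -dy_i, fill = NA_real_)
  valid <- !is.na(b_back)
  score <- if (sum(valid) > 2 && sd(dapi_r1[valid]) > 0 && sd(b_back[valid]) > 0)
    cor(dapi_r1[valid], b_back[valid]) else NA_real_

  structure(list(shift = c(dx = dx_i + ddx, dy = dy_i + ddy),
                 shift_int = c(dx = dx_i, dy = dy_i),
                 score = score,
                 ok = isTRUE(score >= min_score)),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration: shift (%.2f, %.2f) px, score %.3f, %s>\n",
              x$shift[1], x$shift[2], x$score,
              if (x$ok) "ok" else "FAILED"))
  invisible(x)
}

#' Resample an image stack into the round-1 frame
#'
#' Translates every channel by minus the (rounded) estimated shift. Pixels
#' that fall outside the acquired field are filled with the channel median
#' and flagged FALSE in the validity mask attached as \code{$valid}.
#'
#' @param image a \code{multiplex_image}.
#' @param shift numeric (dx, dy) as estimated by [estimate_shift()].
#' @return a \code{multiplex_image} in round-1 coordinates with a logical
#'   \code{$valid} mask.
#' @export
apply_shift <- function(image, shift) {
  if (length(shift) != 2 || any(!is.finite(shift)))
    stopf("apply_shift: shift must be two finite numbers")
  dx <- round(shift[[1]]); dy <- round(shift[[2]])
  out <- image
  out$channels <- lapply(image$channels, function(ch)
    translate_mat(ch, -dx, -dy, fill = median(ch)))
  ones <- matrix(TRUE, nrow(image$channels[[1]]), ncol(image$channels[[1]]))
  out$valid <- translate_mat(ones, -dx, -dy, fill = FALSE) > 0
  out
}

#' Merge a round-1 image with a registered round-2 image
#'
#' @param round1 round-1 \code{multiplex_image}.
#' @param round2_registered round-2 image already moved into the round-1 frame
#'   by [apply_shift()]; its DAPI duplicate is dropped.
#' @return single \code{multiplex_image} carrying all unique channels.
#' @export
merge_rounds <- function(round1, round2_registered) {
  extra <- round2_registered$channels[
    setdiff(names(round2_registered$channels), names(round1$channels))]
  out <- round1
  out$channels <- c(round1$channels, extra)
  out$valid <- round2_registered$valid
  out
}
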