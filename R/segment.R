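#' Segmentation parameters
#'
#' Tunable parameters of the pixel-classification segmentation. Defaults are
#' sized for 1024 px cores at 0.25 um/px: the adaptive Otsu window is 128 px,
#' gland objects must cover at least 500 px (~31 um^2), lumens at least
#' 100 px, and nuclei must have an equivalent diameter of 5-30 px.
#' \code{min_contrast} is the minimum foreground/background mean separation
#' (intensity units on [0, 1]) below which a channel is treated as
#' signal-free instead of thresholded.
#'
#' @param adaptive_block_px adaptive Otsu window size (>= 32).
#' @param min_gland_area_px minimum epithelial object area in pixels.
#' @param min_lumen_area_px minimum lumen object area in pixels.
#' @param nuclei_size_range_px (min, max) nucleus equivalent diameter in px.
#' @param smoothing_sigma_px Gaussian smoothing for the tissue channel sum.
#' @param min_contrast minimum Otsu class separation to accept a threshold.
#' @return list of class \code{seg_params}.
#' @export
seg_params <- function(adaptive_block_px = 128L, min_gland_area_px = 500L,
                       min_lumen_area_px = 100L,
                       nuclei_size_range_px = c(5, 30),
                       smoothing_sigma_px = 2, min_contrast = 0.1) {
  p <- list(adaptive_block_px = as.integer(adaptive_block_px),
            min_gland_area_px = as.integer(min_gland_area_px),
            min_lumen_area_px = as.integer(min_lumen_area_px),
            nuclei_size_range_px = as.numeric(nuclei_size_range_px),
            smoothing_sigma_px = as.numeric(smoothing_sigma_px),
            min_contrast = as.numeric(min_contrast))
  if (p$adaptive_block_px < 32L) stopf("adaptive_block_px must be >= 32")
  if (p$min_gland_area_px < 1L || p$min_lumen_area_px < 1L)
    stopf("minimum object areas must be >= 1 px")
  if (length(p$nuclei_size_range_px) != 2 ||
      p$nuclei_size_range_px[1] >= p$nuclei_size_range_px[2])
    stopf("nuclei_size_range_px must be (min, max) with min < max")
  class(p) <- "seg_params"
  p
}

#' Rescale segmentation parameters to a different image size
#'
#' Areas scale with the square of the linear factor, diameters and windows
#' linearly (window floored at 32 px).
#'
#' @param side image edge length in pixels.
#' @param ref_side reference edge length the defaults are sized for.
#' @param params parameters to rescale.
#' @return rescaled \code{seg_params}.
#' @export
seg_params_for_side <- function(side, ref_side = 1024L, params = seg_params()) {
  s <- side / ref_side
  seg_params(
    adaptive_block_px = max(32L, as.integer(round(params$adaptive_block_px * s))),
    min_gland_area_px = max(1L, as.integer(round(params$min_gland_area_px * s^2))),
    min_lumen_area_px = max(1L, as.integer(round(params$min_lumen_area_px * s^2))),
    nuclei_size_range_px = pmax(c(2, 4), params$nuclei_size_range_px * s),
    smoothing_sigma_px = max(0.8, params$smoothing_sigma_px * s),
    min_contrast = params$min_contrast
  )
}

## Drop labelled/binary components below a minimum area; returns logical mask.
remove_small <- function(mask, min_area) {
  if (!any(mask)) return(mask)
  lab <- mat_label(mask)
  sz <- tabulate(lab[lab > 0])
  keep <- which(sz >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

## Otsu foreground/background mean separation on a sample.
otsu_separation <- function(v, thr) {
  lo <- v[v <= thr]; hi <- v[v > thr]
  if (!length(lo) || !length(hi)) return(0)
  mean(hi) - mean(lo)
}

#' Segment total tissue from the channel sum
#'
#' Each channel is scaled by its 99.9th intensity percentile (so no single
#' bright channel dominates), channels are summed, smoothed, and thresholded
#' with a global Otsu cut. Objects smaller than the minimum gland area are
#' removed and holes smaller than the minimum lumen area are filled. An image
#' with no appreciable foreground/background separation yields an empty mask
#' flagged \code{low_tissue} rather than an error.
#'
#' @param image a \code{multiplex_image} (registered stack).
#' @param params [seg_params()].
#' @return logical tissue mask with attribute \code{low_tissue}.
#' @export
segment_tissue <- function(image, params = seg_params()) {
  chs <- lapply(image$channels, function(ch) {
    q <- quantile(ch, 0.999, names = FALSE)
    if (q <= 0) q <- 1
    clip01(ch / q)
  })
  s <- Reduce(`+`, chs) / length(chs)
  s <- mat_gblur(s, params$smoothing_sigma_px)
  thr1 <- otsu_threshold(as.vector(s))
  if (otsu_separation(as.vector(s), thr1) < params$min_contrast) {
    out <- matrix(FALSE, nrow(s), ncol(s))
    attr(out, "low_tissue") <- TRUE
    return(out)
  }
  # the channel sum carries three populations (glass, unstained tissue,
  # stained signal); the lower of the two 3-class Otsu cuts, computed on log
  # intensity where the glass/tissue separation dominates, is the tissue
  # boundary
  thr <- exp(otsu_thresholds2(as.vector(log(pmax(s, 1e-4))))[1])
  mask <- s > thr
  mask <- remove_small(mask, params$min_gland_area_px)
  holes <- mat_fill_holes(mask) & !mask
  small_holes <- holes & !remove_small(holes, params$min_lumen_area_px)
  mask <- mask | small_holes
  attr(mask, "low_tissue") <- mean(mask) < 0.05
  mask
}

#' Segment epithelial gland objects from the PanEpi channel
#'
#' Adaptive Otsu threshold of the PanEpi channel restricted to tissue;
#' connected components at or above the minimum gland area become gland
#' objects (the object count is the glandularity of the core).
#'
#' @param panepi PanEpi channel matrix.
#' @param tissue logical tissue mask.
#' @param params [seg_params()].
#' @return labelled integer matrix of gland objects (0 = background).
#' @export
segment_epithelium <- function(panepi, tissue, params = seg_params()) {
  empty <- matrix(0L, nrow(panepi), ncol(panepi))
  if (!any(tissue)) return(empty)
  v <- panepi[tissue]
  if (length(unique(v)) < 2L) return(empty)
  thr <- otsu_threshold(v)
  if (otsu_separation(v, thr) < params$min_contrast) return(empty)
  sm <- mat_gblur(panepi, min(1, params$smoothing_sigma_px))
  mask <- adaptive_otsu_mask(sm, roi = tissue,
                             block_px = params$adaptive_block_px)
  mask <- remove_small(mask, params$min_gland_area_px)
  mat_label(mask)
}

#' Stroma as tissue minus epithelium
#'
#' @param tissue logical tissue mask.
#' @param epithelium labelled gland objects (or logical mask).
#' @return logical stroma mask; tissue area equals stroma + epithelium area
#'   exactly, by construction.
#' @export
segment_stroma <- function(tissue, epithelium) {
  if (!all(dim(tissue) == dim(epithelium)))
    stopf("segment_stroma: masks must share the same frame")
  tissue & !(epithelium > 0)
}

#' Glandular lumens by filling and subtracting epithelial objects
#'
#' @param epithelium labelled gland objects (or logical mask).
#' @param params [seg_params()].
#' @return labelled lumen objects (components >= min lumen area).
#' @export
segment_lumen <- function(epithelium, params = seg_params()) {
  mask <- epithelium > 0
  lum <- mat_fill_holes(mask) & !mask
  lum <- remove_small(lum, params$min_lumen_area_px)
  mat_label(lum)
}

#' Segment nuclei from the DAPI channel
#'
#' Adaptive Otsu threshold of DAPI (within tissue when provided), followed by
#' distance-transform watershed splitting of touching nuclei and an
#' equivalent-diameter size filter. The object count is the cellularity of
#' the core.
#'
#' @param dapi DAPI channel matrix.
#' @param params [seg_params()].
#' @param tissue optional logical mask restricting the threshold region.
#' @return labelled integer matrix of nuclei.
#' @export
segment_nuclei <- function(dapi, params = seg_params(), tissue = NULL) {
  roi <- tissue %||% matrix(TRUE, nrow(dapi), ncol(dapi))
  v <- dapi[roi]
  if (length(unique(v)) < 2L)
    stopf("segment_nuclei: degenerate (constant) DAPI channel")
  empty <- matrix(0L, nrow(dapi), ncol(dapi))
  thr <- otsu_threshold(v)
  if (otsu_separation(v, thr) < params$min_contrast) return(empty)
  mask <- adaptive_otsu_mask(dapi, roi = roi,
                             block_px = params$adaptive_block_px)
  if (!any(mask)) return(empty)
  lab <- as_mat(EBImage::watershed(EBImage::distmap(mask * 1), tolerance = 1))
  sz <- tabulate(lab[lab > 0])
  eqd <- 2 * sqrt(sz / pi)
  keep <- which(eqd >= params$nuclei_size_range_px[1] &
                  eqd <= params$nuclei_size_range_px[2])
  out <- empty
  sel <- lab > 0 & lab %in% keep
  out[sel] <- match(lab[sel], keep)
  out
}

#' Marker positivity within stroma by adaptive Otsu
#'
#' The threshold is computed from stromal pixels only, so the positive mask is
#' contained in stroma by construction. An empty stroma yields NULL (a
#' missing measurement, not an error); a marker channel with no appreciable
#' signal yields an all-negative mask.
#'
#' @param marker marker channel matrix.
#' @param stroma logical stroma mask.
#' @param params [seg_params()].
#' @return logical positivity mask inside stroma, or NULL if stroma is empty.
#' @export
marker_positivity <- function(marker, stroma, params = seg_params()) {
  if (!any(stroma)) return(NULL)
  v <- marker[stroma]
  empty <- matrix(FALSE, nrow(marker), ncol(marker))
  if (length(unique(v)) < 2L) return(empty)
  thr <- otsu_threshold(v)
  if (otsu_separation(v, thr) < params$min_contrast) return(empty)
  adaptive_otsu_mask(marker, roi = stroma, block_px = params$adaptive_block_px)
}

#' Full compartment segmentation of a registered core
#'
#' Runs tissue, epithelium, stroma, lumen, nuclei and stromal marker
#' segmentation on a merged (registered) channel stack and returns masks in
#' the shape expected by [quantify_core()].
#'
#' @param image merged \code{multiplex_image} with channels DAPI, CD8, FAP,
#'   CD163, PanEpi and optionally SMA.
#' @param params [seg_params()].
#' @return list of compartment masks (CompartmentMasks).
#' @export
segment_core <- function(image, params = seg_params()) {
  tissue <- segment_tissue(image, params)
  epi <- segment_epithelium(image$channels$PanEpi, tissue, params)
  stroma <- segment_stroma(tissue, epi)
  lum <- segment_lumen(epi, params)
  nuc <- if (any(tissue)) segment_nuclei(image$channels$DAPI, params, tissue)
         else matrix(0L, nrow(tissue), ncol(tissue))
  markers <- intersect(c("CD8", "FAP", "CD163", "SMA"), names(image$channels))
  marker_masks <- lapply(markers, function(m)
    marker_positivity(image$channels[[m]], stroma, params))
  names(marker_masks) <- markers
  marker_masks <- Filter(Negate(is.null), marker_masks)
  list(tissue = tissue, epithelium_objects = epi, stroma = stroma,
       lumen_objects = lum, nuclei_objects = nuc, marker_masks = marker_masks)
}
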