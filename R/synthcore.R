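#' Lesion-class default composition parameters
#'
#' Per-class generator defaults. Lumen, SMA, FAP, CD163 and CD8 levels are the
#' published class medians for benign tissue, MRI false-negative and MRI
#' true-positive prostate lesions (lumen 9.7/8.4/7.6% of tissue; SMA
#' 59.7/55.9/41.3%, FAP 0.3/1.4/3.1%, CD163 1.4/2.5/3.1%, CD8 0.8/1.4/1.5% of
#' stroma). Epithelium and nuclei fractions are reported only graphically in
#' the source cohort, so the defaults here are plausible prostate-histology
#' values that respect the observed ordering (MRI true-positive lesions have
#' the highest epithelial and nuclear content and the most glands).
#'
#' @param lesion_class one of "benign", "mri_neg", "mri_pos".
#' @return named list of target fractions, marker fractions and gland count.
#' @export
lesion_class_defaults <- function(lesion_class = c("benign", "mri_neg", "mri_pos")) {
  lesion_class <- match.arg(lesion_class)
  switch(lesion_class,
    benign = list(
      target_epithelium_fraction = 0.32, target_lumen_fraction = 0.097,
      target_nuclei_fraction = 0.10, n_glands = 12L,
      marker_fractions = c(CD8 = 0.008, FAP = 0.003, CD163 = 0.014, SMA = 0.597)),
    mri_neg = list(
      target_epithelium_fraction = 0.35, target_lumen_fraction = 0.084,
      target_nuclei_fraction = 0.11, n_glands = 14L,
      marker_fractions = c(CD8 = 0.014, FAP = 0.014, CD163 = 0.025, SMA = 0.559)),
    mri_pos = list(
      target_epithelium_fraction = 0.47, target_lumen_fraction = 0.076,
      target_nuclei_fraction = 0.15, n_glands = 20L,
      marker_fractions = c(CD8 = 0.015, FAP = 0.031, CD163 = 0.031, SMA = 0.413))
  )
}

#' Specification of one synthetic TMA core
#'
#' Declares the ground-truth composition of a simulated two-round multiplexed
#' immunofluorescence core: tissue-compartment targets (fractions of tissue
#' area), stromal marker targets (fractions of stroma area), the round-2
#' acquisition shift, and noise. Unset composition fields default to the
#' lesion-class values of [lesion_class_defaults()].
#'
#' @param core_id character identifier.
#' @param lesion_class "benign", "mri_neg" (MRI false-negative cancer) or
#'   "mri_pos" (MRI true-positive cancer).
#' @param target_epithelium_fraction,target_lumen_fraction,target_nuclei_fraction
#'   proportions of tissue area in [0, 1]; epithelium + lumen must not exceed 1.
#' @param marker_fractions named numeric (CD8, FAP, CD163, SMA), proportions of
#'   stroma area in [0, 1].
#' @param n_glands number of epithelial gland objects to render.
#' @param n_nuclei optional fixed nucleus count (otherwise derived from
#'   \code{target_nuclei_fraction}).
#' @param round2_shift integer (dx, dy) pixel translation applied to the
#'   round-2 acquisition.
#' @param noise_level standard deviation of additive Gaussian pixel noise.
#' @param side image edge length in pixels (default 1024, i.e. a 256 um core
#'   tile at 0.25 um/px).
#' @param pixel_size_um pixel size in micrometres.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return object of class \code{core_spec}.
#' @export
core_spec <- function(core_id = "core",
                      lesion_class = c("benign", "mri_neg", "mri_pos"),
                      target_epithelium_fraction = NULL,
                      target_lumen_fraction = NULL,
                      target_nuclei_fraction = NULL,
                      marker_fractions = NULL,
                      n_glands = NULL,
                      n_nuclei = NULL,
                      round2_shift = c(0, 0),
                      noise_level = 0.02,
                      side = 1024L,
                      pixel_size_um = 0.25,
                      seed = 1L) {
  lesion_class <- match.arg(lesion_class)
  d <- lesion_class_defaults(lesion_class)
  spec <- list(
    core_id = as.character(core_id),
    lesion_class = lesion_class,
    target_epithelium_fraction = target_epithelium_fraction %||% d$target_epithelium_fraction,
    target_lumen_fraction = target_lumen_fraction %||% d$target_lumen_fraction,
    target_nuclei_fraction = target_nuclei_fraction %||% d$target_nuclei_fraction,
    marker_fractions = marker_fractions %||% d$marker_fractions,
    n_glands = as.integer(n_glands %||% d$n_glands),
    n_nuclei = if (is.null(n_nuclei)) NULL else as.integer(n_nuclei),
    round2_shift = as.numeric(round2_shift),
    noise_level = as.numeric(noise_level),
    side = as.integer(side),
    pixel_size_um = as.numeric(pixel_size_um),
    seed = as.integer(seed)
  )
  class(spec) <- "core_spec"
  validate_core_spec(spec)
  spec
}

validate_core_spec <- function(spec) {
  check_prop(spec$target_epithelium_fraction, "target_epithelium_fraction")
  check_prop(spec$target_lumen_fraction, "target_lumen_fraction")
  check_prop(spec$target_nuclei_fraction, "target_nuclei_fraction")
  if (spec$target_epithelium_fraction + spec$target_lumen_fraction > 1)
    stopf("infeasible geometry: epithelium + lumen fraction exceeds 1")
  mk <- spec$marker_fractions
  if (!all(c("CD8", "FAP", "CD163", "SMA") %in% names(mk)))
    stopf("marker_fractions must name CD8, FAP, CD163 and SMA")
  check_prop(unname(mk), "marker_fractions")
  if (spec$noise_level < 0) stopf("noise_level must be non-negative")
  if (spec$side < 64) stopf("side must be at least 64 px")
  if (length(spec$round2_shift) != 2 || any(!is.finite(spec$round2_shift)))
    stopf("round2_shift must be two finite numbers")
  invisible(spec)
}

#' @export
print.core_spec <- function(x, ...) {
  cat(sprintf("<core_spec %s: %s, %dx%d px, epi %.3f lumen %.3f nuclei %.3f, seed %d>\n",
              x$core_id, x$lesion_class, x$side, x$side,
              x$target_epithelium_fraction, x$target_lumen_fraction,
              x$target_nuclei_fraction, x$seed))
  invisible(x)
}

#' Construct a multiplexed channel stack
#'
#' Lightweight container for one TMA core acquisition: a named list of
#' channel matrices sharing one frame, plus pixel size and staining round.
#'
#' @param channels named list of numeric matrices in [0, 1].
#' @param pixel_size_um pixel size in micrometres.
#' @param core_id core identifier.
#' @param round staining round (1 or 2).
#' @return object of class \code{multiplex_image}.
#' @export
multiplex_image <- function(channels, pixel_size_um, core_id, round) {
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 core_id = core_id, round = round),
            class = "multiplex_image")
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multiplex_image %s round %d: %dx%d px, channels: %s>\n",
              x$core_id, x$round, d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

## ---- gland geometry -------------------------------------------------------

## Blob-shaped gland: radius as a low-order Fourier perturbation of a circle.
sample_gland_shapes <- function(k, radii) {
  lapply(seq_len(k), function(i) list(
    r = radii[i],
    amp = c(runif(1, 0.04, 0.10), runif(1, 0.03, 0.08), runif(1, 0.02, 0.05)),
    freq = c(2, 3, 5),
    phase = runif(3, 0, 2 * pi)))
}

gland_radius_fun <- function(shape, theta) {
  pert <- shape$amp[1] * sin(shape$freq[1] * theta + shape$phase[1]) +
    shape$amp[2] * sin(shape$freq[2] * theta + shape$phase[2]) +
    shape$amp[3] * sin(shape$freq[3] * theta + shape$phase[3])
  shape$r * (1 + pert)
}

## Stamp one blob into a logical canvas; scale multiplies the radius.
stamp_blob <- function(canvas, cx, cy, shape, scale = 1) {
  n <- nrow(canvas)
  rmax <- shape$r * scale * 1.15
  x0 <- max(1L, floor(cx - rmax)); x1 <- min(n, ceiling(cx + rmax))
  y0 <- max(1L, floor(cy - rmax)); y1 <- min(n, ceiling(cy + rmax))
  if (x0 > x1 || y0 > y1) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  dy <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
  rr <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  inside <- rr <= scale * gland_radius_fun(shape, th)
  canvas[ys, xs] <- canvas[ys, xs] | inside
  canvas
}

render_glands <- function(side, centers, shapes, scale, tissue) {
  g <- matrix(FALSE, side, side)
  for (i in seq_along(shapes)) {
    g <- stamp_blob(g, centers[i, 1], centers[i, 2], shapes[[i]], scale)
  }
  g & tissue
}

## Pairwise repulsion so gland envelopes stay disjoint inside the core disk.
relax_centers <- function(centers, eff_radii, disk_center, disk_radius,
                          n_iter = 250, gap = 3) {
  k <- nrow(centers)
  if (k < 2) return(centers)
  for (it in seq_len(n_iter)) {
    moved <- FALSE
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dvec <- centers[j, ] - centers[i, ]
        d <- sqrt(sum(dvec^2))
        need <- eff_radii[i] + eff_radii[j] + gap
        if (d < need) {
          if (d < 1e-6) { dvec <- c(1, 0); d <- 1 }
          push <- (need - d) / 2 * dvec / d
          centers[i, ] <- centers[i, ] - push
          centers[j, ] <- centers[j, ] + push
          moved <- TRUE
        }
      }
    }
    # keep every gland fully inside the tissue disk
    for (i in seq_len(k)) {
      cv <- centers[i, ] - disk_center
      cd <- sqrt(sum(cv^2))
      lim <- disk_radius - eff_radii[i] - 1
      if (cd > lim && cd > 1e-6) {
        centers[i, ] <- disk_center + cv / cd * lim
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  centers
}

## ---- nuclei placement -----------------------------------------------------

## Grid-accelerated dart throwing: up to n disk centers with minimum
## center-to-center distance min_dist inside the allowed pixel set.
place_disks <- function(allowed_idx, side, n, min_dist) {
  if (n <= 0 || length(allowed_idx) == 0) return(matrix(0, 0, 2))
  cand <- sample(allowed_idx, min(length(allowed_idx), 25L * n))
  cx <- ((cand - 1L) %/% side) + 1L   # column
  cy <- ((cand - 1L) %% side) + 1L    # row
  cell <- ceiling(min_dist)
  gx <- (cx - 1L) %/% cell; gy <- (cy - 1L) %/% cell
  key <- paste(gx, gy)
  occ <- new.env(hash = TRUE, parent = emptyenv())
  acc <- matrix(0, n, 2)
  n_acc <- 0L
  md2 <- min_dist^2
  for (i in seq_along(cand)) {
    ok <- TRUE
    for (ddx in -1:1) {
      for (ddy in -1:1) {
        k <- paste(gx[i] + ddx, gy[i] + ddy)
        pts <- occ[[k]]
        if (!is.null(pts)) {
          d2 <- (pts[, 1] - cx[i])^2 + (pts[, 2] - cy[i])^2
          if (any(d2 < md2)) { ok <- FALSE; break }
        }
      }
      if (!ok) break
    }
    if (ok) {
      n_acc <- n_acc + 1L
      acc[n_acc, ] <- c(cx[i], cy[i])
      occ[[key[i]]] <- rbind(occ[[key[i]]], c(cx[i], cy[i]))
      if (n_acc >= n) break
    }
  }
  acc[seq_len(n_acc), , drop = FALSE]
}

stamp_disks <- function(side, centers, radius) {
  lab <- matrix(0L, side, side)
  if (nrow(centers) == 0) return(lab)
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  for (i in seq_len(nrow(centers))) {
    xs <- centers[i, 1] + off$dx
    ys <- centers[i, 2] + off$dy
    keep <- xs >= 1 & xs <= side & ys >= 1 & ys <= side
    lab[cbind(ys[keep], xs[keep])] <- i
  }
  lab
}

## ---- channel rendering ----------------------------------------------------

BG_OUT <- 0.01   # background outside tissue
BG_IN <- 0.05    # autofluorescence-like background inside tissue

render_channel <- function(signal_mask, tissue, noise_level) {
  side <- nrow(tissue)
  img <- matrix(BG_OUT, side, side)
  img[tissue] <- BG_IN
  if (any(signal_mask)) {
    # lognormal stain intensity above background: separable but not trivial
    intens <- exp(rnorm(sum(signal_mask), log(0.62), 0.22))
    intens[intens < 0.30] <- 0.30
    intens[intens > 0.92] <- 0.92
    img[signal_mask] <- BG_IN + intens
  } else {
    # keep the RNG stream length independent of the mask content
    invisible(rnorm(0))
  }
  if (noise_level > 0) img <- img + rnorm(length(img), 0, noise_level)
  clip01(img)
}

## Threshold a smoothed noise field inside `region` so that exactly
## `n_target` pixels are selected (quantile cut on a continuous field).
field_patch_mask <- function(field, region, n_target) {
  out <- matrix(FALSE, nrow(field), ncol(field))
  n_avail <- sum(region)
  if (n_target <= 0 || n_avail == 0) return(out)
  n_target <- min(n_target, floor(0.98 * n_avail))
  if (n_target < 1) return(out)
  v <- field[region]
  thr <- sort(v, decreasing = TRUE)[n_target]
  out[region & field >= thr] <- TRUE
  out
}

## ---- generator ------------------------------------------------------------

#' Generate one synthetic two-round multiplexed core image with ground truth
#'
#' Renders a circular TMA tissue core containing blob-shaped epithelial gland
#' objects with enclosed glandular lumens, nuclei disks in epithelium and
#' stroma, and stromal marker signal (CD8, FAP, CD163, SMA) as lognormal
#' stain-positive patches. Round 1 carries DAPI, CD8, FAP, CD163 and PanEpi;
#' round 2 carries DAPI and SMA and is translated by \code{spec$round2_shift}
#' to emulate a misregistered second acquisition. Rendered compartment
#' fractions land within about 2 percentage points of the requested targets
#' (discretization); the stored ground truth is the exact pixel count of the
#' emitted masks. Identical seeds give bit-identical output.
#'
#' @param spec a [core_spec()].
#' @return list with elements \code{round1}, \code{round2} (multiplex images)
#'   and \code{truth}: \code{masks} (tissue, labelled epithelium, stroma,
#'   labelled lumen, labelled nuclei, marker masks in the round-1 frame),
#'   \code{true_fractions} (exact [quantify_core()] of the masks) and
#'   \code{true_shift}.
#' @export
generate_core <- function(spec) {
  validate_core_spec(spec)
  with_rng(spec$seed, {
    side <- spec$side
    ctr <- (side + 1) / 2
    R <- 0.47 * side

    xs <- matrix(seq_len(side), side, side, byrow = TRUE)
    ys <- matrix(seq_len(side), side, side)
    tissue <- (xs - ctr)^2 + (ys - ctr)^2 <= R^2
    n_tissue <- sum(tissue)

    epi_f <- spec$target_epithelium_fraction
    lum_f <- spec$target_lumen_fraction
    gland_area_target <- (epi_f + lum_f) * n_tissue

    ## -- glands
    gf <- matrix(FALSE, side, side)
    centers <- matrix(0, 0, 2)
    shapes <- list()
    scale <- 1
    if (epi_f > 0 && spec$n_glands > 0) {
      k <- spec$n_glands
      r0 <- sqrt(gland_area_target / k / pi)
      radii <- r0 * runif(k, 0.75, 1.25)
      radii <- radii * sqrt(gland_area_target / sum(pi * radii^2))
      shapes <- sample_gland_shapes(k, radii)
      eff <- radii * 1.28
      ang <- runif(k, 0, 2 * pi)
      rad <- (R - eff - 2) * sqrt(runif(k))
      rad[rad < 0] <- 0
      centers <- cbind(ctr + rad * cos(ang), ctr + rad * sin(ang))
      centers <- relax_centers(centers, eff, c(ctr, ctr), R)
      gf <- render_glands(side, centers, shapes, scale, tissue)
      # one corrective pass towards the target filled-gland area
      for (pass in 1:2) {
        a <- sum(gf)
        if (a > 0 && abs(a / n_tissue - (epi_f + lum_f)) > 0.005) {
          scale <- scale * min(1.12, sqrt(gland_area_target / a))
          gf <- render_glands(side, centers, shapes, scale, tissue)
        }
      }
    }

    ## -- lumens: concentric holes, guaranteed enclosed by their gland
    lum <- matrix(FALSE, side, side)
    if (lum_f > 0 && sum(gf) > 0) {
      h <- min(0.62, sqrt(lum_f * n_tissue / sum(gf)))
      lum <- render_glands(side, centers, shapes, scale * h, tissue) & gf
      a <- sum(lum)
      if (a > 0) {
        h <- min(0.62, h * sqrt(lum_f * n_tissue / a))
        lum <- render_glands(side, centers, shapes, scale * h, tissue) & gf
      }
    }

    epi <- gf & !lum
    stroma <- tissue & !epi
    marker_region <- tissue & !gf
    n_stroma <- sum(stroma)

    ## -- stromal marker patches (fixed RNG order, thresholds depend only on
    ##    the target fraction, so higher targets give supersets)
    marker_names <- c("CD8", "FAP", "CD163", "SMA")
    fields <- lapply(marker_names, function(m)
      mat_gblur(matrix(rnorm(side^2), side, side), sigma = side / 64))
    names(fields) <- marker_names
    marker_masks <- lapply(marker_names, function(m)
      field_patch_mask(fields[[m]], marker_region,
                       round(spec$marker_fractions[[m]] * n_stroma)))
    names(marker_masks) <- marker_names

    ## -- nuclei
    r_nuc <- max(3L, as.integer(round(5 * side / 1024)))
    n_nuc <- spec$n_nuclei %||%
      as.integer(round(spec$target_nuclei_fraction * n_tissue /
                         (pi * r_nuc^2)))
    nuc_region <- tissue & !lum
    allowed <- mat_erode(nuc_region, r_nuc + 1L)
    nuc_centers <- place_disks(which(allowed), side, n_nuc, 2 * r_nuc + 2)
    nuclei_lab <- stamp_disks(side, nuc_centers, r_nuc)
    nuclei <- nuclei_lab > 0

    ## -- channels
    nl <- spec$noise_level
    round1 <- multiplex_image(list(
      DAPI = render_channel(nuclei, tissue, nl),
      CD8 = render_channel(marker_masks$CD8, tissue, nl),
      FAP = render_channel(marker_masks$FAP, tissue, nl),
      CD163 = render_channel(marker_masks$CD163, tissue, nl),
      PanEpi = render_channel(epi, tissue, nl)
    ), spec$pixel_size_um, spec$core_id, 1L)

    shift <- round(spec$round2_shift)
    round2 <- multiplex_image(list(
      DAPI = translate_mat(render_channel(nuclei, tissue, nl),
                           shift[1], shift[2], fill = BG_OUT),
      SMA = translate_mat(render_channel(marker_masks$SMA, tissue, nl),
                          shift[1], shift[2], fill = BG_OUT)
    ), spec$pixel_size_um, spec$core_id, 2L)

    masks <- list(
      tissue = tissue,
      epithelium_objects = mat_label(epi),
      stroma = stroma,
      lumen_objects = mat_label(lum),
      nuclei_objects = nuclei_lab,
      marker_masks = marker_masks
    )
    truth <- list(
      masks = masks,
      true_fractions = quantify_core(masks, core_id = spec$core_id,
                                     lesion_class = spec$lesion_class,
                                     pixel_size_um = spec$pixel_size_um),
      true_shift = shift
    )
    list(round1 = round1, round2 = round2, truth = truth)
  })
}
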