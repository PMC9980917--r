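## Optical-density stain vectors (rows: hematoxylin, DAB brown, permanent
## red), Ruifrok-Johnston style; configurable in the feature extractor.
default_stain_matrix <- function() {
  m <- rbind(hema = c(0.650, 0.704, 0.286),
             dab = c(0.268, 0.570, 0.776),
             red = c(0.210, 0.851, 0.478))
  m / sqrt(rowSums(m^2))
}

BF_CLASSES <- c("empty", "FAP_pos", "SMA_pos", "other_tissue")

#' Generate a synthetic chromogenic FAP/SMA/hematoxylin core image
#'
#' Renders an RGB brightfield core on a white background using a Beer-Lambert
#' stain model: all tissue carries a hematoxylin counterstain, FAP-positive
#' patches add DAB (brown) and SMA-positive patches add permanent red, with
#' lognormal per-pixel stain concentrations. Patch geometry comes from
#' thresholded low-pass noise fields; FAP and SMA regions are disjoint.
#'
#' @param fap_fraction,sma_fraction target positive fractions of tissue area.
#' @param side image edge length in pixels.
#' @param noise_level additive RGB noise standard deviation.
#' @param seed integer seed.
#' @return list: \code{rgb} (side x side x 3 array in [0,1]), \code{class_map}
#'   (factor-coded integer matrix, 1..4 = empty/FAP_pos/SMA_pos/other_tissue),
#'   and \code{truth} with exact pixel-count fractions.
#' @export
generate_brightfield_core <- function(fap_fraction, sma_fraction,
                                      side = 256L, noise_level = 0.01,
                                      seed = 1L) {
  check_prop(fap_fraction, "fap_fraction")
  check_prop(sma_fraction, "sma_fraction")
  if (fap_fraction + sma_fraction > 1)
    stopf("fap_fraction + sma_fraction must not exceed 1")
  with_rng(seed, {
    ctr <- (side + 1) / 2
    R <- 0.47 * side
    xs <- matrix(seq_len(side), side, side, byrow = TRUE)
    ys <- matrix(seq_len(side), side, side)
    tissue <- (xs - ctr)^2 + (ys - ctr)^2 <= R^2
    n_t <- sum(tissue)

    f_sma <- mat_gblur(matrix(rnorm(side^2), side, side), sigma = side / 32)
    f_fap <- mat_gblur(matrix(rnorm(side^2), side, side), sigma = side / 48)
    sma <- field_patch_mask(f_sma, tissue, round(sma_fraction * n_t))
    fap <- field_patch_mask(f_fap, tissue & !sma, round(fap_fraction * n_t))

    class_map <- matrix(1L, side, side)            # empty
    class_map[tissue] <- 4L                        # other tissue
    class_map[sma] <- 3L
    class_map[fap] <- 2L

    M <- default_stain_matrix()
    n_px <- side^2
    c_h <- matrix(0, side, side)
    c_h[tissue] <- exp(rnorm(n_t, log(0.50), 0.20))
    c_d <- matrix(0, side, side)
    c_d[fap] <- exp(rnorm(sum(fap), log(1.0), 0.25))
    c_r <- matrix(0, side, side)
    c_r[sma] <- exp(rnorm(sum(sma), log(0.9), 0.25))

    rgb <- array(0, c(side, side, 3))
    for (ch in 1:3) {
      od <- c_h * M["hema", ch] + c_d * M["dab", ch] + c_r * M["red", ch]
      rgb[, , ch] <- clip01(exp(-od) + rnorm(n_px, 0, noise_level))
    }
    list(rgb = rgb, class_map = class_map,
         truth = list(tissue = tissue,
                      fap_fraction = sum(fap) / n_t,
                      sma_fraction = sum(sma) / n_t,
                      tissue_pixels = n_t))
  })
}

#' Per-pixel feature matrix for brightfield classification
#'
#' RGB values, optical densities, color-deconvolved stain channels
#' (hematoxylin/DAB/red), and Gaussian-smoothed deconvolved channels at two
#' scales.
#'
#' @param rgb side x side x 3 array in [0,1].
#' @param stain_matrix 3x3 stain OD matrix (rows = stains).
#' @param scales smoothing scales (pixels) for the context features.
#' @return numeric matrix, one row per pixel (column-major pixel order).
#' @export
pixel_features <- function(rgb, stain_matrix = default_stain_matrix(),
                           scales = c(2, 4)) {
  side <- dim(rgb)[1]
  n <- side * dim(rgb)[2]
  od <- -log(pmax(rgb, 0.01))
  od_flat <- matrix(od, n, 3)
  deconv <- od_flat %*% solve(t(stain_matrix))
  feats <- cbind(matrix(rgb, n, 3), od_flat, deconv)
  colnames(feats) <- c("R", "G", "B", "odR", "odG", "odB",
                       "hema", "dab", "red")
  for (s in scales) {
    for (k in 1:3) {
      ch <- matrix(deconv[, k], side)
      feats <- cbind(feats, as.vector(mat_gblur(ch, s)))
      colnames(feats)[ncol(feats)] <-
        paste0(c("hema", "dab", "red")[k], "_s", s)
    }
  }
  feats
}

#' Sample sparse training scribbles from a reference class map
#'
#' @param class_map integer matrix coded 1..4 (empty/FAP_pos/SMA_pos/other).
#' @param n_per_class pixels to annotate per class.
#' @param seed integer seed.
#' @return data.frame: \code{idx} (pixel index, column-major), \code{class}
#'   (factor over all four classes).
#' @export
make_scribbles <- function(class_map, n_per_class = 400L, seed = 1L) {
  with_rng(seed, {
    out <- lapply(seq_along(BF_CLASSES), function(k) {
      idx <- which(class_map == k)
      if (length(idx) == 0) return(NULL)
      data.frame(idx = sample(idx, min(n_per_class, length(idx))),
                 class = BF_CLASSES[k], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out$class <- factor(out$class, levels = BF_CLASSES)
    out
  })
}

#' Train the 4-class brightfield pixel classifier
#'
#' Random-forest ensemble over per-pixel color, optical-density, stain-
#' deconvolution and multi-scale context features. A quarter of the scribbles
#' is held out to report pixel accuracy. Deterministic for a fixed seed.
#'
#' @param images list of RGB arrays (or a single array).
#' @param scribbles list of scribble data.frames from [make_scribbles()],
#'   aligned with \code{images}; jointly they must cover all four classes.
#' @param seed integer seed.
#' @param num_trees forest size.
#' @return list of class \code{bf_classifier}: \code{rf}, \code{classes},
#'   \code{holdout_accuracy}, \code{stain_matrix}.
#' @export
train_pixel_classifier <- function(images, scribbles, seed = 1L,
                                   num_trees = 120L) {
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  if (is.data.frame(scribbles)) scribbles <- list(scribbles)
  sm <- default_stain_matrix()
  train <- do.call(rbind, lapply(seq_along(images), function(i) {
    f <- pixel_features(images[[i]], sm)
    cbind(as.data.frame(f[scribbles[[i]]$idx, , drop = FALSE]),
          class = scribbles[[i]]$class)
  }))
  present <- table(train$class)
  if (any(present == 0))
    stopf("train_pixel_classifier: missing scribbles for class(es): %s",
          paste(names(present)[present == 0], collapse = ", "))
  with_rng(seed, {
    n <- nrow(train)
    holdout <- sample.int(n, max(1L, round(0.25 * n)))
    rf <- ranger::ranger(class ~ ., data = train[-holdout, ],
                         num.trees = num_trees, seed = as.integer(seed),
                         num.threads = 1L)
    pred <- stats::predict(rf, train[holdout, ], num.threads = 1L)$predictions
    acc <- mean(pred == train$class[holdout])
    structure(list(rf = rf, classes = BF_CLASSES, holdout_accuracy = acc,
                   stain_matrix = sm),
              class = "bf_classifier")
  })
}

#' Classify a brightfield image and quantify tissue-normalized fractions
#'
#' Per-pixel argmax class over the four stain classes; FAP and SMA positive
#' pixel counts are normalized by the total tissue pixel count (all non-empty
#' pixels). An image with no tissue yields missing fractions.
#'
#' @param model a \code{bf_classifier}.
#' @param rgb RGB array.
#' @return list: \code{quant} (one-row data.frame: fap_fraction, sma_fraction,
#'   tissue_pixels) and \code{class_map} (integer matrix coded 1..4).
#' @export
classify_and_quantify <- function(model, rgb) {
  feats <- as.data.frame(pixel_features(rgb, model$stain_matrix))
  pred <- stats::predict(model$rf, feats, num.threads = 1L)$predictions
  cls <- match(as.character(pred), model$classes)
  class_map <- matrix(cls, dim(rgb)[1], dim(rgb)[2])
  n_tissue <- sum(cls != 1L)
  quant <- data.frame(
    fap_fraction = if (n_tissue) sum(cls == 2L) / n_tissue else NA_real_,
    sma_fraction = if (n_tissue) sum(cls == 3L) / n_tissue else NA_real_,
    tissue_pixels = n_tissue)
  list(quant = quant, class_map = class_map)
}

#' Concordance between fluorescence and brightfield FAP measurements
#'
#' Pearson correlation of FAP fractions across cores measured in both
#' modalities.
#'
#' @param fap_fluorescence,fap_brightfield paired per-core FAP fractions.
#' @return a \code{stat_result} (Pearson r as \code{effect}); a constant
#'   modality gives a missing result with a warning.
#' @export
fluorescence_concordance <- function(fap_fluorescence, fap_brightfield) {
  keep <- !is.na(fap_fluorescence) & !is.na(fap_brightfield)
  if (sum(keep) < 3)
    stopf("fluorescence_concordance: need at least 3 paired cores")
  correlate(fap_fluorescence[keep], fap_brightfield[keep], "pearson")
}
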