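#' Per-core quantification from compartment masks
#'
#' Turns a set of compartment masks into the per-core measurement row:
#' tissue-compartment area fractions (of total tissue), object counts per
#' tissue area, and stromal marker fractions (marker-positive area over total
#' stroma area). All ratios are exact pixel-count ratios of the masks.
#'
#' @param masks list with elements \code{tissue} (logical),
#'   \code{epithelium_objects} (labelled integer matrix), \code{stroma}
#'   (logical), \code{lumen_objects} (labelled), \code{nuclei_objects}
#'   (labelled) and \code{marker_masks} (named list of logical masks inside
#'   stroma, typically CD8/FAP/CD163/SMA).
#' @param core_id,lesion_class identifiers copied into the output row.
#' @param pixel_size_um pixel size, for counts per mm^2 of tissue.
#' @param registration_ok if FALSE the round-2 marker (SMA) is recorded as
#'   missing, mirroring quality-based exclusion of unregistrable cores.
#' @return one-row data.frame (a CoreQuant): fractions, counts, densities,
#'   marker fractions and a \code{qc_flags} string.
#' @export
quantify_core <- function(masks, core_id = "core", lesion_class = NA_character_,
                          pixel_size_um = 0.25, registration_ok = TRUE) {
  n_tissue <- sum(masks$tissue)
  marker_names <- names(masks$marker_masks) %||% character()
  flags <- character()

  if (n_tissue == 0) {
    out <- data.frame(core_id = core_id, lesion_class = lesion_class,
                      tissue_px = 0L,
                      epithelium_fraction = NA_real_, stroma_fraction = NA_real_,
                      nuclei_fraction = NA_real_, lumen_fraction = NA_real_,
                      gland_count = NA_integer_, lumen_count = NA_integer_,
                      nuclei_count = NA_integer_,
                      gland_density_mm2 = NA_real_, lumen_density_mm2 = NA_real_,
                      nuclei_density_mm2 = NA_real_,
                      stringsAsFactors = FALSE)
    for (m in marker_names) out[[paste0(tolower(m), "_fraction")]] <- NA_real_
    out$qc_flags <- "empty_tissue"
    return(out)
  }

  epi <- masks$epithelium_objects > 0
  n_epi <- sum(epi)
  n_stroma <- sum(masks$stroma)
  n_lumen <- sum(masks$lumen_objects > 0)
  n_nuclei <- sum(masks$nuclei_objects > 0)
  n_labels <- function(lab) length(setdiff(unique(as.vector(lab)), 0L))
  area_mm2 <- n_tissue * (pixel_size_um / 1000)^2

  out <- data.frame(
    core_id = core_id, lesion_class = lesion_class,
    tissue_px = n_tissue,
    epithelium_fraction = n_epi / n_tissue,
    stroma_fraction = n_stroma / n_tissue,
    nuclei_fraction = n_nuclei / n_tissue,
    lumen_fraction = n_lumen / n_tissue,
    gland_count = n_labels(masks$epithelium_objects),
    lumen_count = n_labels(masks$lumen_objects),
    nuclei_count = n_labels(masks$nuclei_objects),
    stringsAsFactors = FALSE
  )
  out$gland_density_mm2 <- out$gland_count / area_mm2
  out$lumen_density_mm2 <- out$lumen_count / area_mm2
  out$nuclei_density_mm2 <- out$nuclei_count / area_mm2

  for (m in marker_names) {
    col <- paste0(tolower(m), "_fraction")
    if (n_stroma == 0) {
      out[[col]] <- NA_real_
      flags <- c(flags, "empty_stroma")
    } else if (identical(m, "SMA") && !registration_ok) {
      out[[col]] <- NA_real_
      flags <- c(flags, "registration_failed")
    } else {
      out[[col]] <- sum(masks$marker_masks[[m]] & masks$stroma) / n_stroma
    }
  }
  if (n_tissue / length(masks$tissue) < 0.05) flags <- c(flags, "low_tissue")
  out$qc_flags <- paste(unique(flags), collapse = ";")
  out
}

#' Aggregate replicate cores to one patient record
#'
#' Averages replicate-core measurements per lesion class (unweighted mean over
#' non-missing cores), attaches clinical metadata and applies the outcome
#' exclusion rules: patients with a missing outcome or follow-up shorter than
#' 3 weeks are flagged as excluded, with the reason recorded.
#'
#' @param cores data.frame of [quantify_core()] rows for one patient, with a
#'   \code{lesion_class} column.
#' @param meta one-row data.frame or list of patient metadata; must contain
#'   \code{patient_id}; \code{event} and \code{time_months} are used for the
#'   exclusion rules when present.
#' @return one-row data.frame with class-prefixed means (e.g.
#'   \code{mri_pos_fap_fraction}), metadata columns, and \code{included} /
#'   \code{exclusion_reason}.
#' @export
aggregate_patient <- function(cores, meta) {
  if (is.null(meta$patient_id)) stopf("meta must contain patient_id")
  num_cols <- setdiff(names(cores)[vapply(cores, is.numeric, logical(1))],
                      "tissue_px")
  classes <- unique(cores$lesion_class)
  out <- data.frame(patient_id = meta$patient_id, stringsAsFactors = FALSE)
  any_usable <- FALSE
  for (cl in classes) {
    sub <- cores[cores$lesion_class == cl, , drop = FALSE]
    usable <- sub[sub$qc_flags == "" | !grepl("empty_tissue", sub$qc_flags), ,
                  drop = FALSE]
    for (v in num_cols) {
      vals <- usable[[v]]
      vals <- vals[!is.na(vals)]
      out[[paste0(cl, "_", v)]] <- if (length(vals)) mean(vals) else NA_real_
      if (length(vals)) any_usable <- TRUE
    }
    out[[paste0(cl, "_n_cores")]] <- nrow(usable)
  }
  for (v in setdiff(names(meta), "patient_id")) out[[v]] <- meta[[v]]

  reason <- NULL
  if (!any_usable) reason <- "no_usable_cores"
  if (!is.null(meta$event) && is.na(meta$event)) reason <- c(reason, "missing_outcome")
  if (!is.null(meta$time_months) &&
      (is.na(meta$time_months) || meta$time_months < 21 / 30.4375))
    reason <- c(reason, "followup_lt_3wk")
  out$included <- is.null(reason)
  out$exclusion_reason <- if (is.null(reason)) "" else paste(reason, collapse = ";")
  out
}
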