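#' Default end-to-end run configuration
#'
#' A compact demonstration configuration: a synthetic cohort whose cores are
#' rendered, registered, segmented, quantified, aggregated and analyzed. The
#' demo scale (small patient count, reduced tile size) keeps a full run to a
#' couple of minutes; all sizes are configurable.
#'
#' @param n_patients patients in the simulated cohort.
#' @param cores_per_class replicate cores per lesion class per patient.
#' @param side rendered core tile edge length in pixels.
#' @param seed master seed; all stage seeds derive from it.
#' @param family_size Bonferroni family size for the univariable screen.
#' @param min_score minimum registration score; failures mark the core's SMA
#'   measurement missing.
#' @param max_shift_px magnitude range of the simulated round-2 shifts.
#' @return named list (a RunConfig).
#' @export
default_run_config <- function(n_patients = 12L, cores_per_class = 1L,
                               side = 192L, seed = 1L, family_size = 53L,
                               min_score = 0.5, max_shift_px = 10L) {
  list(n_patients = as.integer(n_patients),
       cores_per_class = as.integer(cores_per_class),
       side = as.integer(side),
       seed = as.integer(seed),
       family_size = as.integer(family_size),
       min_score = min_score,
       max_shift_px = as.integer(max_shift_px))
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; fields missing from the file keep their defaults.
#' @return RunConfig list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  do.call(default_run_config, cfg[names(formals(default_run_config))])
}

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + 104729 * i) %% 2147483587) + 1L
}

#' Run the full pipeline: simulate, register, segment, quantify, analyze
#'
#' Simulates a cohort and its core images, registers round 2 onto round 1 via
#' the shared DAPI channel, segments compartments and stromal markers,
#' quantifies each core, aggregates replicate cores per patient with the
#' outcome exclusion rules, and runs the statistical layer (PTEN x FAP
#' cross-tab, Bonferroni-corrected univariable Cox screen, Kaplan-Meier /
#' log-rank on median-dichotomized FAP). Writes per-core and per-patient
#' CSVs, analysis CSVs and a JSON manifest that accounts for every core and
#' patient (loaded = analyzed + excluded). Identical configurations reproduce
#' all outputs byte-for-byte.
#'
#' @param config RunConfig from [default_run_config()] or [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (missing(out_dir)) stopf("run_pipeline: out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- seg_params_for_side(config$side)

  cohort <- generate_cohort(cohort_spec(
    n_patients = config$n_patients,
    cores_per_patient_per_class = config$cores_per_class,
    seed = derive_seed(config$seed, 1)))
  core_tab <- attr(cohort, "cores")

  core_rows <- vector("list", nrow(core_tab))
  for (i in seq_len(nrow(core_tab))) {
    cr <- core_tab[i, ]
    cseed <- derive_seed(config$seed, 100 + i)
    shift <- with_rng(cseed, sample(-config$max_shift_px:config$max_shift_px, 2,
                                    replace = TRUE))
    spec <- core_spec(
      core_id = sprintf("%s_%s_%d", cr$patient_id, cr$lesion_class,
                        cr$replicate),
      lesion_class = cr$lesion_class,
      marker_fractions = c(CD8 = cr$cd8_fraction, FAP = cr$fap_fraction,
                           CD163 = cr$cd163_fraction, SMA = cr$sma_fraction),
      round2_shift = shift, side = config$side, seed = cseed)
    core <- generate_core(spec)
    reg <- estimate_shift(core$round1$channels$DAPI,
                          core$round2$channels$DAPI,
                          min_score = config$min_score)
    merged <- merge_rounds(core$round1, apply_shift(core$round2, reg$shift))
    masks <- segment_core(merged, params)
    q <- quantify_core(masks, core_id = spec$core_id,
                       lesion_class = cr$lesion_class,
                       pixel_size_um = spec$pixel_size_um,
                       registration_ok = reg$ok)
    q$patient_id <- cr$patient_id
    q$reg_shift_dx <- reg$shift[["dx"]]
    q$reg_shift_dy <- reg$shift[["dy"]]
    q$reg_score <- reg$score
    core_rows[[i]] <- q
  }
  cores_df <- do.call(rbind, core_rows)

  meta_cols <- c("patient_id", "age", "ggg", "ptnm", "capra", "damico",
                 "pten", "erg", "event", "time_months")
  patients <- do.call(rbind, lapply(unique(cores_df$patient_id), function(pid) {
    aggregate_patient(cores_df[cores_df$patient_id == pid, ],
                      as.list(cohort[cohort$patient_id == pid, meta_cols]))
  }))
  analysis <- patients[patients$included, , drop = FALSE]

  ## statistical layer on the measured (not simulated) quantities
  fap <- analysis$mri_pos_fap_fraction
  stats_out <- list()
  if (sum(!is.na(fap)) >= 4 && length(unique(stats::na.omit(fap))) > 1) {
    di <- dichotomize(fap, "median")
    if (length(unique(stats::na.omit(analysis$pten))) == 2 &&
        di$n_high > 0 && di$n_low > 0) {
      ct <- crosstab(analysis$pten, ifelse(di$high, "high", "low"))
      stats_out$crosstab <- data.frame(
        row = rownames(ct$counts)[row(ct$counts)],
        col = colnames(ct$counts)[col(ct$counts)],
        count = as.vector(ct$counts), row_pct = as.vector(ct$row_pct),
        test = ct$test, p = ct$p)
    }
    if (sum(analysis$event, na.rm = TRUE) >= 2 && di$n_high > 1 &&
        di$n_low > 1) {
      km <- tryCatch(km_logrank(analysis$time_months, analysis$event,
                                ifelse(di$high, "FAP_high", "FAP_low")),
                     error = function(e) NULL)
      if (!is.null(km)) {
        stats_out$km <- km$curves
        stats_out$km_summary <- data.frame(
          logrank_chisq = km$logrank_chisq, p = km$p,
          hr = if (!is.null(km$cox)) km$cox$table$hr else NA_real_)
      }
    }
  }
  screen_vars <- grep("^mri_pos_.*_fraction$", names(analysis), value = TRUE)
  screen <- tryCatch(
    univariable_screen(analysis, screen_vars,
                       family_size = config$family_size),
    error = function(e) NULL)

  write_out <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(write_out(cores_df, "cores.csv"),
             write_out(patients, "patients.csv"))
  if (!is.null(screen)) paths <- c(paths, write_out(screen, "screen.csv"))
  if (!is.null(stats_out$crosstab))
    paths <- c(paths, write_out(stats_out$crosstab, "crosstab_pten_fap.csv"))
  if (!is.null(stats_out$km)) {
    paths <- c(paths, write_out(stats_out$km, "km_curves.csv"),
               write_out(stats_out$km_summary, "km_summary.csv"))
  }

  excl <- table(patients$exclusion_reason[!patients$included])
  manifest <- list(
    config = config,
    n_cores_loaded = nrow(cores_df),
    n_cores_registration_failed = sum(cores_df$reg_score < config$min_score),
    n_patients_loaded = nrow(patients),
    n_patients_analyzed = nrow(analysis),
    n_patients_excluded = nrow(patients) - nrow(analysis),
    exclusion_reasons = as.list(excl),
    outputs = lapply(stats::setNames(paths, basename(paths)), function(p)
      unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
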