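#' Specification of a synthetic survival cohort
#'
#' Declares the statistical structure of a simulated prostatectomy cohort:
#' per-patient stromal marker fractions drawn from a Gaussian-copula latent
#' model with prescribed rank correlations, clinical covariates, and a
#' proportional-hazards outcome (exponential baseline, independent exponential
#' censoring, administrative cap).
#'
#' Defaults follow the published cohort: marker rank correlations FAP-CD8
#' 0.44, FAP-CD163 0.43, FAP-SMA -0.30, SMA-CD8 -0.17, SMA-CD163 -0.21; the
#' continuous hazard coefficients correspond to the reported per-percentage-
#' point hazard ratios of 1.04 (FAP) and 0.96 (SMA), i.e. log-hazards of
#' about +3.9 and -4.1 per unit fraction.
#'
#' @param n_patients number of patients (>= 2).
#' @param cores_per_patient_per_class replicate TMA cores per lesion class.
#' @param log_hazard_fap,log_hazard_sma log hazard ratios per unit marker
#'   fraction (or per high/low indicator when \code{dichotomize_hazard}).
#' @param baseline_hazard events per month in a marker-free patient.
#' @param censoring_rate independent exponential censoring rate per month.
#' @param max_followup administrative censoring horizon in months.
#' @param marker_correlation named target Spearman correlations; recognized
#'   names: FAP_CD8, FAP_CD163, FAP_SMA, SMA_CD8, SMA_CD163, CD8_CD163.
#' @param dichotomize_hazard if TRUE the hazard acts on dichotomized marker
#'   indicators instead of continuous fractions (used for calibration studies
#'   at a prescribed hazard ratio).
#' @param hazard_cutpoint dichotomization rule for the hazard indicators when
#'   \code{dichotomize_hazard}: "median" (50% prevalence) or "top_decile"
#'   (10% prevalence).
#' @param seed integer seed.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 280L,
                        cores_per_patient_per_class = 2L,
                        log_hazard_fap = 100 * log(1.04),
                        log_hazard_sma = 100 * log(0.96),
                        baseline_hazard = 0.0025,
                        censoring_rate = 0.007,
                        max_followup = 120,
                        marker_correlation = NULL,
                        dichotomize_hazard = FALSE,
                        hazard_cutpoint = c("median", "top_decile"),
                        seed = 1L) {
  hazard_cutpoint <- match.arg(hazard_cutpoint)
  rho <- c(FAP_CD8 = 0.44, FAP_CD163 = 0.43, FAP_SMA = -0.30,
           SMA_CD8 = -0.17, SMA_CD163 = -0.21, CD8_CD163 = 0.30)
  if (!is.null(marker_correlation)) {
    bad <- setdiff(names(marker_correlation), names(rho))
    if (length(bad)) stopf("unknown marker_correlation names: %s",
                           paste(bad, collapse = ", "))
    rho[names(marker_correlation)] <- marker_correlation
  }
  sp <- list(n_patients = as.integer(n_patients),
             cores_per_patient_per_class = as.integer(cores_per_patient_per_class),
             log_hazard_fap = log_hazard_fap,
             log_hazard_sma = log_hazard_sma,
             baseline_hazard = baseline_hazard,
             censoring_rate = censoring_rate,
             max_followup = max_followup,
             marker_correlation = rho,
             dichotomize_hazard = isTRUE(dichotomize_hazard),
             hazard_cutpoint = hazard_cutpoint,
             seed = as.integer(seed))
  if (sp$n_patients < 2L) stopf("n_patients must be >= 2")
  if (sp$baseline_hazard <= 0 || sp$censoring_rate <= 0 || sp$max_followup <= 0)
    stopf("rates and max_followup must be positive")
  if (any(abs(rho) > 1)) stopf("correlations must lie in [-1, 1]")
  class(sp) <- "cohort_spec"
  sp
}

## Spearman -> Pearson correlation of the Gaussian copula.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

## Nearest positive-definite clip of a correlation matrix.
make_pd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) > 1e-8) return(S)
  v <- pmax(e$values, 1e-6)
  S2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  D <- diag(1 / sqrt(diag(S2)))
  D %*% S2 %*% D
}

## Marker marginals per lesion class: location = published class median,
## spread chosen so the MRI-positive FAP distribution has its observed long
## right tail (about 10% of patients above a 0.20 fraction).
marker_marginal <- function(u, marker, lesion_class) {
  med <- lesion_class_defaults(lesion_class)$marker_fractions[[marker]]
  if (marker == "SMA") {
    plogis(qlogis(med) + 0.55 * qnorm(u))
  } else {
    sdlog <- if (marker == "FAP") 1.41 else 0.80
    pmin(0.95, exp(log(med) + sdlog * qnorm(u)))
  }
}

#' Generate a synthetic patient cohort with known statistical structure
#'
#' Draws per-patient marker fractions for the three lesion classes from a
#' shared 4-marker Gaussian copula (so the requested rank correlations hold
#' within each class), attaches clinical covariates with the published
#' cross-sectional associations (PTEN loss enriched in FAP-high patients, ERG
#' positivity in SMA-high patients), and simulates outcome under exponential
#' proportional hazards with independent exponential censoring and an
#' administrative follow-up cap.
#'
#' @param cspec a [cohort_spec()].
#' @return data.frame with one row per patient: class-prefixed marker
#'   fractions (e.g. \code{mri_pos_fap_fraction}), covariates (age, ggg,
#'   ptnm, capra, damico, pten, erg), \code{event} and \code{time_months}.
#'   A per-core long table is attached as attribute \code{"cores"}.
#' @export
generate_cohort <- function(cspec) {
  if (!inherits(cspec, "cohort_spec")) stopf("cspec must be a cohort_spec")
  n <- cspec$n_patients
  with_rng(cspec$seed, {
    rho <- cspec$marker_correlation
    mk <- c("FAP", "SMA", "CD8", "CD163")
    S <- diag(4); dimnames(S) <- list(mk, mk)
    pair <- function(a, b) {
      nm <- paste(a, b, sep = "_")
      if (!nm %in% names(rho)) nm <- paste(b, a, sep = "_")
      rho[[nm]]
    }
    for (i in 1:3) for (j in (i + 1):4)
      S[i, j] <- S[j, i] <- spearman_to_pearson(pair(mk[i], mk[j]))
    S <- make_pd(S)
    L <- chol(S)

    classes <- c("benign", "mri_neg", "mri_pos")
    z <- matrix(rnorm(n * 4), n, 4) %*% L
    colnames(z) <- mk
    u <- pnorm(z)

    pat <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (cl in classes) {
      for (m in mk) {
        pat[[paste0(cl, "_", tolower(m), "_fraction")]] <-
          marker_marginal(u[, m], m, cl)
      }
    }

    fap <- pat$mri_pos_fap_fraction
    sma <- pat$mri_pos_sma_fraction
    fap_high <- fap > median(fap)
    sma_high <- sma > median(sma)
    fap_hz <- if (cspec$hazard_cutpoint == "median") fap_high
              else dichotomize(fap, "top_decile")$high
    sma_hz <- if (cspec$hazard_cutpoint == "median") sma_high
              else dichotomize(sma, "top_decile")$high

    pat$age <- round(rnorm(n, 64, 6.5))
    pat$ggg <- sample(1:5, n, replace = TRUE,
                      prob = c(6, 112, 143, 10, 31) / 302)
    pat$ptnm <- sample(2:4, n, replace = TRUE, prob = c(0.65, 0.25, 0.10))
    pat$capra <- pmin(10L, pmax(0L, round(rnorm(n, 3.5, 2))))
    pat$damico <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    pat$pten <- ifelse(rbinom(n, 1, 0.073 + 0.165 * fap_high) == 1,
                       "neg", "pos")
    pat$erg <- ifelse(rbinom(n, 1, 0.20 + 0.21 * sma_high) == 1,
                      "pos", "neg")

    ## linear predictor centered at typical marker values so baseline_hazard
    ## is the hazard of a typical patient (centering only rescales the
    ## baseline; the proportional-hazards structure is unchanged)
    ctr_def <- lesion_class_defaults("mri_pos")$marker_fractions
    xf <- if (cspec$dichotomize_hazard) as.numeric(fap_hz) else fap
    xs <- if (cspec$dichotomize_hazard) as.numeric(sma_hz) else sma
    cf <- if (cspec$dichotomize_hazard) 0.5 else ctr_def[["FAP"]]
    cs_ <- if (cspec$dichotomize_hazard) 0.5 else ctr_def[["SMA"]]
    lp <- cspec$log_hazard_fap * (xf - cf) + cspec$log_hazard_sma * (xs - cs_)
    t_event <- rexp(n, rate = cspec$baseline_hazard * exp(lp))
    t_cens <- rexp(n, rate = cspec$censoring_rate)
    pat$event <- as.integer(t_event <= t_cens & t_event <= cspec$max_followup)
    pat$time_months <- pmin(t_event, t_cens, cspec$max_followup)

    # replicate-core long table: patient value jittered on the latent scale
    k <- cspec$cores_per_patient_per_class
    cores <- expand.grid(patient_id = pat$patient_id, lesion_class = classes,
                         replicate = seq_len(k), stringsAsFactors = FALSE)
    cores <- cores[order(cores$patient_id, cores$lesion_class,
                         cores$replicate), , drop = FALSE]
    rownames(cores) <- NULL
    for (m in mk) {
      base_u <- u[match(cores$patient_id, pat$patient_id), m]
      jit <- pnorm(qnorm(pmin(pmax(base_u, 1e-6), 1 - 1e-6)) +
                     rnorm(nrow(cores), 0, 0.15))
      col <- numeric(nrow(cores))
      for (cl in classes) {
        sel <- cores$lesion_class == cl
        col[sel] <- marker_marginal(jit[sel], m, cl)
      }
      cores[[paste0(tolower(m), "_fraction")]] <- col
    }
    attr(pat, "cores") <- cores
    class(pat) <- c("stromascope_cohort", "data.frame")
    pat
  })
}
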