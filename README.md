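# stromascope

Quantification of tumor-stroma composition from multiplexed IHC images of
prostate tissue-microarray (TMA) cores, and its association with MRI lesion
class and patient outcome.

## The problem

A substantial minority of clinically significant prostate cancers are
invisible on multiparametric MRI. One tissue-level correlate of MRI
visibility is the composition of the tumor stroma: MRI-visible lesions carry
more fibroblast-rich, desmoplastic stroma. Studying this requires an image
analysis chain that turns two-round multiplexed immunofluorescence (mfIHC)
of TMA cores — round 1: DAPI, CD8, FAP, CD163, PanEpi; round 2 after
bleaching: DAPI, SMA — into per-core stromal marker fractions, and a
statistical layer that relates those fractions to lesion class
(benign / MRI false-negative / MRI true-positive) and to biochemical
recurrence after prostatectomy.

`stromascope` implements that chain end to end:

* **`synthcore` / `synthcohort`** — synthetic two-round core images with
  exact ground-truth masks, and survival cohorts with known copula
  correlation structure and a known proportional-hazards law, so every
  downstream stage is testable without any external data.
* **`register`** — translation-only registration of round 2 onto round 1 via
  spectral cross-correlation of the shared DAPI channel, with subpixel
  refinement and a quality score; failed registrations mark the core's SMA
  measurement missing.
* **`segment`** — Otsu-based pixel classification: tissue (3-class Otsu on
  the log channel sum), epithelial gland objects (adaptive block-wise Otsu of
  PanEpi), stroma = tissue − epithelium (exact conservation), lumens by
  fill-and-subtract, nuclei by adaptive Otsu + watershed, and stromal marker
  positivity thresholded within stroma only.
* **`brightfield`** — a random-forest pixel classifier (color deconvolution +
  multiscale features) for chromogenic FAP(brown)/SMA(red)/hematoxylin
  stains, with fractions normalized to total tissue.
* **`quantify`** — exact pixel-count fractions per core; replicate-core
  averaging to patients with REMARK-style exclusion accounting.
* **`cohortstats`** — normality-routed group comparisons, correlations,
  biomarker dichotomization (median / fixed / decile), Fisher/chi-square
  cross-tabs, Bonferroni-corrected univariable Cox screens, Kaplan-Meier +
  log-rank, Efron-tie Cox fits with Wald intervals, Schoenfeld PH
  diagnostics, and a DeLong test for correlated ROC curves.
* **`run_pipeline()`** — simulate → register → segment → quantify → stats,
  with deterministic, byte-reproducible CSV outputs and a JSON manifest.

The core statistic throughout is an area fraction: marker-positive stromal
area / total stromal area per core (for brightfield, / total tissue area),
averaged over a patient's replicate cores, then dichotomized (e.g. FAP high
vs low at the median) and carried into Cox models
`h(t | x) = h0(t) · exp(βᵀx)`.

## Worked example

Render a synthetic MRI-true-positive core with a misregistered second round,
register it, segment it, and quantify:

```r
library(stromascope)

spec <- core_spec("demo", "mri_pos", round2_shift = c(7, -4),
                  side = 384L, seed = 7)
core <- generate_core(spec)

reg <- estimate_shift(core$round1$channels$DAPI, core$round2$channels$DAPI)
reg
#> <registration: shift (7.00, -4.00) px, score 0.947, ok>

merged <- merge_rounds(core$round1, apply_shift(core$round2, reg$shift))
masks  <- segment_core(merged, seg_params_for_side(384L))
quantify_core(masks, core_id = "demo", lesion_class = "mri_pos")
#>   epithelium_fraction stroma_fraction lumen_fraction nuclei_fraction  fap_fraction sma_fraction
#>                0.4686          0.5314         0.0756          0.1527        0.0306       0.4078
core$truth$true_fractions   # exact ground truth
#>                0.4716          0.5284         0.0760          0.1539        0.0310       0.4130
```

The round-2 shift of (7, −4) px is recovered exactly, and every measured
fraction is within half a percentage point of the rendered truth — e.g.
stromal FAP 3.06% measured vs 3.10% true, the level typical of MRI-visible
lesions.

Simulate a 300-patient cohort whose true median-dichotomized FAP hazard
ratio is 2.75, then ask the survival layer to find it:

```r
co <- generate_cohort(cohort_spec(n_patients = 300,
                                  log_hazard_fap = log(2.75),
                                  log_hazard_sma = 0,
                                  dichotomize_hazard = TRUE, seed = 11))
di <- dichotomize(co$mri_pos_fap_fraction, "median")
round(di$cutoff, 4)
#> 0.0296
km <- km_logrank(co$time_months, co$event,
                 factor(ifelse(di$high, "FAP_high", "FAP_low"),
                        levels = c("FAP_low", "FAP_high")))
km
#> <KM/log-rank: chisq 6.381 (df 1), p = 0.01153, n = 300>
km$cox
#> <Cox fit: n = 300, events = 56, converged: TRUE>
#>             covariate  beta hr ci_lo ci_hi p_wald
#> 1 FAP_high_vs_FAP_low 0.691  2  1.16  3.45 0.0133
```

The median cutoff lands at a 2.96% FAP fraction (the published cohort's was
3.3%), patients above it recur faster (log-rank p = 0.012), and the Cox
hazard ratio estimate of 2.0 (95% CI 1.16–3.45) brackets one plausible draw
at n = 300 around the true 2.75.

Run the whole pipeline on a small simulated cohort:

```r
run_pipeline(default_run_config(n_patients = 12, seed = 1), "out/")
```

writes `cores.csv`, `patients.csv`, `screen.csv`, `crosstab_pten_fap.csv`,
`km_curves.csv`, `km_summary.csv` and a `manifest.json` accounting for every
core and patient. A shell entry point with the same verbs lives in
`inst/cli/stromascope.R`.

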