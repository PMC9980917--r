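---
title: "Quantifying tumor stroma in multiplexed IHC tissue microarray cores"
author: "stromascope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor stroma in multiplexed IHC tissue microarray cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromascope)
```

## The problem

Prostate cancers that are visible on multiparametric MRI (PI-RADS 3-5) behave
differently from cancers the MRI misses. One candidate explanation is the
composition of the tumor stroma: MRI-visible lesions carry more
desmoplastic, fibroblast-rich stroma. To study this quantitatively, tissue
microarray (TMA) cores from prostatectomy specimens are stained in two
multiplexed immunofluorescence rounds — round 1 with DAPI, CD8 (cytotoxic T
cells), FAP (cancer-associated fibroblasts), CD163 (macrophages) and a pooled
pan-epithelial stain (PanEpi); round 2, after bleaching, with DAPI and SMA
(smooth muscle) — and each core is segmented into tissue compartments so that
stromal marker content can be expressed as an area fraction of the stroma.
Those fractions are then carried into survival models of biochemical
recurrence (BCR) after prostatectomy.

`stromascope` implements that entire computational chain: image registration
across staining rounds, compartment segmentation, marker quantification,
aggregation of replicate cores to patients, and the statistical layer. Since
suitable image/cohort data are rarely public, the package also ships a
synthetic-data module that generates core images with exact ground truth and
cohorts with known statistical structure; every stage of the pipeline is
validated against those known answers.

## The synthetic core generator

`generate_core()` renders a circular tissue core (default 1024 x 1024 px at
0.25 um/px, matching a 20x scan) with:

* **Epithelial glands** — blob-shaped objects (a circle whose radius is
  perturbed by a low-order Fourier series), placed with pairwise repulsion so
  they remain distinct objects. Glandular **lumens** are concentric holes
  carved inside glands, so they are always enclosed — exactly the topology
  the fill-and-subtract lumen rule detects.
* **Nuclei** — disks placed by grid-accelerated dart throwing with a minimum
  separation, in both epithelium and stroma (not in lumens).
* **Stromal markers** (CD8, FAP, CD163, SMA) — thresholded low-pass Gaussian
  noise fields restricted to extraglandular tissue, selected by pixel-count
  quantile so the rendered fraction matches the target almost exactly.
  Stain intensity is lognormal above background, which keeps Otsu
  thresholding honest (separable but not trivial).
* **Two rounds** — round 2 (DAPI + SMA) is translated by an integer pixel
  shift to emulate a misregistered second acquisition; additive Gaussian
  noise on every channel.

Ground truth is stored as the *exact pixel-count ratios* of the emitted
masks, not the requested targets; rendered fractions land within about 2
percentage points of the targets (discretization).

Class-conditional defaults follow the published cohort: lumen fraction
9.7% / 8.4% / 7.6% of tissue and marker medians SMA 59.7/55.9/41.3%,
FAP 0.3/1.4/3.1%, CD163 1.4/2.5/3.1%, CD8 0.8/1.4/1.5% of stroma for
benign / MRI false-negative / MRI true-positive cores. Epithelium (0.32 /
0.35 / 0.47), nuclei (0.10 / 0.11 / 0.15) and gland counts are reported only
graphically in the source study, so those defaults are our own choices of
plausible prostate-histology values respecting the published ordering
(MRI-positive lesions: more epithelium, more nuclei, more glands, less
stroma). Distribution spreads around the class medians are likewise free
parameters of the generator, not calibrated claims.

## Registration

Restaining does not move the slide relative to the scanner beyond a
translation, so registration is translation-only. `estimate_shift()`
cross-correlates the mean-subtracted DAPI channels on the FFT grid and
refines the peak with a separable three-point parabolic fit; the score is
the Pearson correlation of the overlap at the integer shift. A score below
`min_score` (default 0.5 — a design choice; no quality threshold is
published) marks registration as failed, and the affected core's round-2
(SMA) measurement becomes missing rather than wrong, mirroring
quality-based exclusions in TMA studies. `apply_shift()` moves round 2 into
round-1 coordinates, filling out-of-view pixels with the channel median and
flagging them in a validity mask.

## Segmentation

All thresholding is built on Otsu's criterion (maximum between-class
variance), implemented at unit histogram resolution for integer data — which
makes the threshold exactly shift-equivariant — and 256 bins otherwise.
"Adaptive" Otsu computes thresholds in blocks (default 128 px; the original
pipeline names the method but no window) and interpolates them bilinearly
between block centers; blocks whose intensity range is less than half the
global range (i.e. signal-free regions where Otsu would split noise) fall
back to the global threshold.

* **Tissue**: each channel is scaled by its 99.9th percentile (so no single
  bright channel dominates — a choice; the original scaling is unstated),
  channels are summed and smoothed. The sum carries three populations —
  glass, unstained tissue, stained signal — so a single Otsu cut separates
  signal from everything else and loses unstained stroma. We therefore take
  the lower of the two cuts of a three-class Otsu computed on log intensity,
  where the glass/tissue separation dominates. On synthetic cores this
  recovers tissue at Jaccard 0.99 against truth.
* **Epithelium**: adaptive Otsu of PanEpi within tissue; connected components
  of at least `min_gland_area_px` (default 500 px ~ 31 um^2) become gland
  objects; the object count is the glandularity.
* **Stroma** = tissue minus epithelium, so tissue area = stroma + epithelium
  exactly, on every core.
* **Lumen** = fill-holes(epithelium) minus epithelium, components >=
  `min_lumen_area_px` (default 100 px).
* **Nuclei**: adaptive Otsu of DAPI, distance-transform watershed to split
  touching nuclei (the original pipeline's declumping behavior is unstated;
  watershed is our choice), equivalent-diameter filter 5-30 px.
* **Markers**: adaptive Otsu computed within stroma only, so positivity masks
  are contained in stroma by construction; computed per core (per-slide
  pooling is unstated in the source). An empty stroma yields a missing
  measurement, not an error. A channel whose foreground/background mean
  separation is below `min_contrast` (0.1 intensity units) is treated as
  signal-free — without this guard Otsu happily splits pure noise.

## Brightfield (chromogenic) path

For the FAP(brown, DAB)/SMA(red)/hematoxylin double stain there is no
epithelial costain, so fractions are of *total tissue* (all non-empty
pixels), not stroma. `train_pixel_classifier()` fits a random forest over
per-pixel RGB, optical density, color-deconvolved stain channels
(hematoxylin/DAB/red, Ruifrok-Johnston-style vectors, configurable) and
Gaussian-smoothed stain channels at 2 and 4 px. Training labels are sparse
scribbles over the four classes (empty, FAP-positive, SMA-positive, other
tissue); a quarter is held out to report pixel accuracy. The synthetic
brightfield generator renders the same geometry vocabulary under a
Beer-Lambert stain model, and the feature bank of the original interactive
tool is unreported, so the classifier design is validated on synthetic data
only.

## Quantification and aggregation

`quantify_core()` reports exact pixel-count ratios: compartment fractions of
total tissue, object counts per mm^2 of tissue, and marker fractions of
stroma. `aggregate_patient()` averages replicate cores per lesion class with
an unweighted mean over non-missing cores (the source says only
"averaging"; whether pixel counts were re-pooled is unstated — fraction
averaging chosen) and applies the outcome exclusions: missing outcome
status, or follow-up under 3 weeks. Exclusions are logged with reasons so the
pipeline manifest can account for every core and patient (REMARK-style:
loaded = analyzed + excluded).

## Cohort simulation

`generate_cohort()` draws per-patient marker fractions from a 4-marker
Gaussian copula whose pairwise Spearman targets default to the published
values (FAP-CD8 0.44, FAP-CD163 0.43, FAP-SMA -0.30, SMA-CD8 -0.17,
SMA-CD163 -0.21), converting rank to Pearson correlations by
2 sin(pi rho / 6). Marginals are lognormal (FAP sdlog 1.41, chosen so that
with the published median of 3.1-3.3% about 10% of MRI-positive patients
exceed a 20% fraction, matching the published patient histogram) or
logit-normal (SMA). PTEN loss is enriched in FAP-high patients (7.3% vs
23.8%, the published 2x2 margins) and ERG positivity in SMA-high patients.

Outcome follows exponential proportional hazards — the simplest PH-consistent
law; no published claim identifies the hazard shape — with independent
exponential censoring and a 120-month administrative cap. Default log-hazards
+3.9/-4.1 per unit fraction correspond to the published per-percentage-point
hazard ratios of 1.04 (FAP) and 0.96 (SMA); the linear predictor is centered
at typical marker values so `baseline_hazard` (0.0025/month) is a typical
patient's hazard. Baseline and censoring rates are not published; the
defaults were fixed a priori to give a realistic 15-25% event fraction over
10 years of follow-up, consistent with biochemical-recurrence rates in
prostatectomy series. For calibration studies at a prescribed hazard ratio
the hazard can act on dichotomized indicators (`dichotomize_hazard`, median
or top-decile cutpoint).

## Statistical layer

Group comparisons pre-test normality per group (Lilliefors-corrected
Kolmogorov-Smirnov, since population moments are estimated; plain KS tables
would be anticonservative) and use Student's t or the asymptotic,
tie-corrected Mann-Whitney U accordingly. Correlations are Pearson or
Spearman, two-sided. Dichotomization is strict ("high" = value > cutoff,
matching the published ">3.3%" convention); decile rules mark exactly the
top or bottom 10% with stable tie-breaking. Cross-tabulations use Fisher's
exact test for every 2x2 table and Pearson's chi-square for larger tables —
the published 2x2 p-values (0.708, 0.008, 0.025) reproduce exactly under
Fisher, which pins down what "when applicable" meant. The univariable Cox
screen corrects Wald p-values by a Bonferroni family of 53 (all clinical +
image-analysis variables screened together; inferred from the published
corrected values, and configurable). Cox models use Efron tie handling (the
original method is unstated), proportional hazards are checked with scaled
Schoenfeld residuals, and the DeLong test for two correlated ROC curves is
implemented via placement values (AUC equals Mann-Whitney U scaled — an
identity the tests exploit as an oracle, alongside a cross-check against
pROC). The ROC outcome is operationalized as the binary event indicator at
end of follow-up; the original horizon is undefined, so this is documented
as an interpretation.

## Numerical and scale choices

Identical seeds give bit-identical images, cohorts and pipeline CSVs; all
randomness flows through one seeded generator per call with the caller's RNG
state preserved. Demonstration and validation runs use reduced problem sizes
chosen as the package's own working scale — synthetic cores at 224-384 px
(the geometry and recovery behavior is scale-free; segmentation parameters
rescale via `seg_params_for_side()`), brightfield tiles at 160-224 px,
survival calibrations at 200-500 replicates with n = 150-300 patients. The
demo pipeline (`default_run_config()`: 12 patients, three cores each,
192 px tiles) completes in about a minute.

## What passing tests do and do not show

The synthetic generator emulates compartment geometry, class-conditional
composition, two-round misregistration, stain separability and a known
survival law. It does not emulate optics (PSF, chromatic shifts),
autofluorescence spectra, stain bleed-through, tissue folds and debris,
multi-tile stitching, or inter-batch staining variation. Recovery of ground
truth within tolerance therefore validates the *algorithmic chain* — that
segmentation, registration, quantification and statistics compute what they
claim on data whose answer is known — not the biological accuracy of any
particular threshold on real slides. Published cohort-specific quantities
(median fractions, hazard ratios, the fluorescence/chromogenic concordance
of r = 0.753 measured on real tissue) are used to calibrate the generator,
and are not reproduction targets; the package's concordance on clean
synthetic pairs is intentionally much higher.

## Known limitations

* Translation-only registration: rotation or scale drift between rounds is
  out of scope.
* Marker thresholds are per-core; very low-signal cores rely on the
  min-contrast guard rather than a slide-level prior.
* The brightfield classifier is validated on synthetic stains; real DAB/red
  co-localization and counterstain variation would need real scribbles.
* Cohort covariates (GGG, pTNM, CAPRA) are drawn with published margins but
  are not linked to the markers beyond the PTEN/ERG associations, so the
  multivariable adjustment structure of the original study is only partially
  emulated.
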