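toy_masks <- function() {
  tis <- matrix(FALSE, 10, 10); tis[1:10, 1:8] <- TRUE      # 80 px tissue
  epi <- matrix(0L, 10, 10); epi[1:5, 1:4] <- 1L            # 20 px epithelium
  lum <- matrix(0L, 10, 10); lum[2:3, 2:3] <- 1L            # 4 px lumen
  epi[lum > 0] <- 0L                                        # 16 px epithelium
  nuc <- matrix(0L, 10, 10); nuc[8, 1] <- 1L; nuc[9, 3] <- 2L
  fap <- matrix(FALSE, 10, 10); fap[7:10, 5:8] <- TRUE      # 16 px in stroma
  list(tissue = tis, epithelium_objects = epi,
       stroma = tis & !(epi > 0), lumen_objects = lum, nuclei_objects = nuc,
       marker_masks = list(FAP = fap))
}

test_that("quantify_core reports exact hand-computable pixel ratios", {
  q <- quantify_core(toy_masks(), pixel_size_um = 10)
  expect_identical(q$tissue_px, 80L)
  expect_equal(q$epithelium_fraction, 16 / 80)
  expect_equal(q$stroma_fraction, 64 / 80)
  expect_equal(q$lumen_fraction, 4 / 80)
  expect_equal(q$nuclei_fraction, 2 / 80)
  expect_equal(q$fap_fraction, 16 / 64)
  expect_equal(q$gland_count, 1)
  expect_equal(q$nuclei_count, 2)
  # counts normalized per tissue area: 80 px * (10 um)^2 = 0.008 mm^2
  expect_equal(q$gland_density_mm2, 1 / 0.008)
  expect_equal(q$epithelium_fraction + q$stroma_fraction, 1, tolerance = 1e-9)
})

test_that("degenerate cores propagate missingness instead of failing", {
  m <- toy_masks()
  m$epithelium_objects[m$tissue] <- 1L   # all-epithelium core
  m$stroma <- m$tissue & !(m$epithelium_objects > 0)
  q <- quantify_core(m)
  expect_equal(q$epithelium_fraction, 1)
  expect_equal(q$stroma_fraction, 0)
  expect_true(is.na(q$fap_fraction))
  expect_match(q$qc_flags, "empty_stroma")

  m2 <- toy_masks()
  m2$tissue[] <- FALSE
  q2 <- quantify_core(m2)
  expect_true(is.na(q2$epithelium_fraction))
  expect_match(q2$qc_flags, "empty_tissue")

  q3 <- quantify_core(toy_masks(), registration_ok = FALSE)
  expect_false(is.na(q3$fap_fraction))  # FAP is round-1, unaffected
  m3 <- toy_masks(); m3$marker_masks$SMA <- m3$marker_masks$FAP
  q4 <- quantify_core(m3, registration_ok = FALSE)
  expect_true(is.na(q4$sma_fraction))
  expect_match(q4$qc_flags, "registration_failed")
})

test_that("patient aggregation is an unweighted, order-invariant core mean", {
  mk_core <- function(fap, cl = "mri_pos")
    data.frame(core_id = "c", lesion_class = cl, tissue_px = 100L,
               epithelium_fraction = 0.4, stroma_fraction = 0.6,
               nuclei_fraction = 0.1, lumen_fraction = 0.08,
               gland_count = 10, lumen_count = 5, nuclei_count = 50,
               gland_density_mm2 = 1, lumen_density_mm2 = 1,
               nuclei_density_mm2 = 1, fap_fraction = fap, qc_flags = "")
  meta <- list(patient_id = "P1", event = 0L, time_months = 24)
  one <- aggregate_patient(mk_core(0.02), meta)
  expect_equal(one$mri_pos_fap_fraction, 0.02)
  two <- aggregate_patient(rbind(mk_core(0.02), mk_core(0.04)), meta)
  expect_equal(two$mri_pos_fap_fraction, 0.03)
  rev2 <- aggregate_patient(rbind(mk_core(0.04), mk_core(0.02)), meta)
  expect_equal(two$mri_pos_fap_fraction, rev2$mri_pos_fap_fraction)
  # missing cores are dropped from the mean
  nc <- rbind(mk_core(0.02), mk_core(NA))
  expect_equal(aggregate_patient(nc, meta)$mri_pos_fap_fraction, 0.02)
})

test_that("exclusion accounting reproduces injected missingness exactly", {
  mk_core <- function() data.frame(core_id = "c", lesion_class = "mri_pos",
                                   tissue_px = 100L, epithelium_fraction = 0.4,
                                   stroma_fraction = 0.6, nuclei_fraction = 0.1,
                                   lumen_fraction = 0.08, gland_count = 1,
                                   lumen_count = 1, nuclei_count = 1,
                                   gland_density_mm2 = 1, lumen_density_mm2 = 1,
                                   nuclei_density_mm2 = 1, fap_fraction = 0.05,
                                   qc_flags = "")
  metas <- list(
    list(patient_id = "A", event = 1L, time_months = 36),
    list(patient_id = "B", event = NA_integer_, time_months = 12),   # no outcome
    list(patient_id = "C", event = 0L, time_months = 0.3),           # < 3 weeks
    list(patient_id = "D", event = 1L, time_months = 60))
  recs <- do.call(rbind, lapply(metas, function(m) aggregate_patient(mk_core(), m)))
  expect_equal(sum(!recs$included), 2)
  expect_match(recs$exclusion_reason[recs$patient_id == "B"], "missing_outcome")
  expect_match(recs$exclusion_reason[recs$patient_id == "C"], "followup_lt_3wk")
  kept <- recs[recs$included, ]
  expect_true(all(kept$time_months >= 21 / 30.4375))
  expect_true(all(!is.na(kept$event)))
})
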