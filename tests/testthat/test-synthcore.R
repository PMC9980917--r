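test_that("identical seeds give bit-identical cores", {
  spec <- core_spec("d", "mri_neg", side = 160L, seed = 7,
                    round2_shift = c(3, -2))
  a <- generate_core(spec)
  b <- generate_core(spec)
  expect_identical(a, b)
})

test_that("zero epithelium target yields a background PanEpi channel", {
  spec <- core_spec("e0", "benign", target_epithelium_fraction = 0,
                    target_lumen_fraction = 0, side = 160L, seed = 3)
  core <- generate_core(spec)
  expect_equal(core$truth$true_fractions$epithelium_fraction, 0)
  expect_equal(core$truth$true_fractions$gland_count, 0)
  # PanEpi carries only in-tissue background: nothing near stain intensity
  pe <- core$round1$channels$PanEpi
  expect_lt(quantile(pe[core$truth$masks$tissue], 0.999), 0.2)
})

test_that("stored truth equals an independent pixel recount and hits targets", {
  spec <- core_spec("t", "mri_pos", target_epithelium_fraction = 0.40,
                    target_lumen_fraction = 0.08,
                    marker_fractions = c(CD8 = 0.015, FAP = 0.031,
                                         CD163 = 0.031, SMA = 0.413),
                    side = 320L, seed = 5)
  core <- generate_core(spec)
  m <- core$truth$masks
  tf <- core$truth$true_fractions
  n_t <- sum(m$tissue)
  # exact recount
  expect_identical(tf$epithelium_fraction, sum(m$epithelium_objects > 0) / n_t)
  expect_identical(tf$lumen_fraction, sum(m$lumen_objects > 0) / n_t)
  expect_identical(tf$stroma_fraction, sum(m$stroma) / n_t)
  expect_identical(tf$fap_fraction,
                   sum(m$marker_masks$FAP & m$stroma) / sum(m$stroma))
  # discretization tolerance against the requested targets
  expect_lt(abs(tf$epithelium_fraction - 0.40), 0.02)
  expect_lt(abs(tf$lumen_fraction - 0.08), 0.02)
  expect_lt(abs(tf$fap_fraction - 0.031), 0.02)
  expect_lt(abs(tf$nuclei_fraction - spec$target_nuclei_fraction), 0.02)
})

test_that("mask invariants hold: disjointness, containment, conservation", {
  fx <- cached_core("mri_pos", side = 320L, seed = 42L)
  m <- fx$core$truth$masks
  epi <- m$epithelium_objects > 0
  expect_equal(sum(m$stroma & epi), 0)
  expect_equal(sum((m$lumen_objects > 0) & epi), 0)
  expect_true(all(!epi | m$tissue))
  expect_true(all(!m$stroma | m$tissue))
  expect_identical(sum(m$tissue), sum(m$stroma) + sum(epi))
  for (mm in m$marker_masks) expect_true(all(!mm | m$stroma))
  # lumens are enclosed: filling epithelium holes recovers every lumen pixel
  filled <- EBImage::fillHull((epi) * 1)
  expect_true(all(filled[m$lumen_objects > 0] > 0))
})

test_that("raising the FAP target never shrinks the rendered FAP mask", {
  base <- list(core_id = "m", lesion_class = "mri_pos", side = 160L, seed = 9)
  counts <- vapply(c(0.005, 0.02, 0.08, 0.2), function(f) {
    spec <- do.call(core_spec, c(base, list(
      marker_fractions = c(CD8 = 0.015, FAP = f, CD163 = 0.031, SMA = 0.413))))
    sum(generate_core(spec)$truth$masks$marker_masks$FAP)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("class defaults reproduce the published FAP/SMA ordering", {
  d <- lapply(c("benign", "mri_neg", "mri_pos"), lesion_class_defaults)
  fap <- vapply(d, function(x) x$marker_fractions[["FAP"]], numeric(1))
  sma <- vapply(d, function(x) x$marker_fractions[["SMA"]], numeric(1))
  expect_true(all(diff(fap) > 0))   # benign < mri_neg < mri_pos
  expect_true(all(diff(sma) < 0))   # benign > mri_neg > mri_pos
  # and on simulated cores (truth fractions, 12 per class)
  tf <- lapply(c("benign", "mri_pos"), function(cl)
    vapply(1:12, function(i)
      generate_core(core_spec("o", cl, side = 128L, seed = 100 + i)
                    )$truth$true_fractions$fap_fraction, numeric(1)))
  wt <- wilcox.test(tf[[2]], tf[[1]], alternative = "greater", exact = FALSE)
  expect_lt(wt$p.value, 0.01)
})

test_that("infeasible geometry is a parameter error", {
  expect_error(core_spec("x", "benign", target_epithelium_fraction = 0.95,
                         target_lumen_fraction = 0.10), "infeasible")
  expect_error(core_spec("x", "benign", target_epithelium_fraction = -0.1),
               "proportion")
  expect_error(core_spec("x", "benign", noise_level = -1), "noise_level")
})
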