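test_that("tissue, compartments and markers recover ground truth on a synthetic core", {
  fx <- cached_core("mri_pos", side = 320L, seed = 42L, shift = c(7, -4))
  sg <- segment_fixture(fx)
  truth <- fx$core$truth
  tf <- truth$true_fractions
  q <- sg$quant

  jacc <- sum(sg$masks$tissue & truth$masks$tissue) /
    sum(sg$masks$tissue | truth$masks$tissue)
  expect_gte(jacc, 0.95)
  for (col in c("epithelium_fraction", "stroma_fraction", "lumen_fraction",
                "nuclei_fraction")) {
    expect_lt(abs(q[[col]] - tf[[col]]), 0.02)
  }
  expect_lte(abs(q$gland_count - tf$gland_count), 1)
  # conservation, exact
  expect_identical(sum(sg$masks$tissue),
                   sum(sg$masks$stroma) + sum(sg$masks$epithelium_objects > 0))
})

test_that("stroma complements epithelium within tissue", {
  tis <- matrix(TRUE, 20, 20)
  epi <- matrix(0L, 20, 20)
  expect_true(all(segment_stroma(tis, epi)))
  epi[] <- 1L
  expect_false(any(segment_stroma(tis, epi)))
  expect_error(segment_stroma(tis, matrix(0L, 10, 10)), "frame")
})

test_that("lumen detection is the fill-and-subtract of gland objects", {
  p <- seg_params(min_lumen_area_px = 4, min_gland_area_px = 10)
  solid <- matrix(0L, 40, 40); solid[10:25, 10:25] <- 1L
  expect_equal(max(segment_lumen(solid, p)), 0)
  annulus <- matrix(0L, 40, 40)
  annulus[8:30, 8:30] <- 1L
  annulus[14:24, 14:24] <- 0L   # enclosed hole
  lum <- segment_lumen(annulus, p)
  expect_equal(max(lum), 1)
  expect_identical(unname(which(lum > 0)),
                   unname(which(annulus == 0 &
                                EBImage::fillHull(annulus) > 0)))
})

test_that("signal-free channels yield empty segmentations, not artifacts", {
  side <- 128L
  tis <- matrix(FALSE, side, side)
  tis[(row(tis) - 64)^2 + (col(tis) - 64)^2 <= 50^2] <- TRUE
  flat <- withr::with_seed(1, matrix(0.05 + rnorm(side^2, 0, 0.02), side))
  p <- seg_params_for_side(side)
  expect_equal(max(segment_epithelium(flat, tis, p)), 0)
  expect_equal(max(segment_epithelium(matrix(0, side, side), tis, p)), 0)
  expect_equal(max(segment_nuclei(flat, p, tis)), 0)
  expect_error(segment_nuclei(matrix(0.5, side, side), p), "constant|degenerate")
  m <- marker_positivity(flat, tis, p)
  expect_lt(sum(m) / sum(tis), 0.005)
  expect_null(marker_positivity(flat, matrix(FALSE, side, side), p))
})

test_that("a blank acquisition gives an empty tissue mask with a low-tissue flag", {
  side <- 128L
  blank <- multiplex_image(
    lapply(setNames(1:3, c("DAPI", "PanEpi", "FAP")), function(i)
      withr::with_seed(i, matrix(0.01 + rnorm(side^2, 0, 0.003), side))),
    0.25, "blank", 1L)
  m <- segment_tissue(blank, seg_params_for_side(side))
  expect_false(any(m))
  expect_true(attr(m, "low_tissue"))
})

test_that("nuclei counting is accurate for non-touching nuclei", {
  spec <- core_spec("nuc", "benign", n_nuclei = 400L, side = 384L, seed = 13)
  core <- generate_core(spec)
  expect_equal(core$truth$true_fractions$nuclei_count, 400)
  p <- seg_params_for_side(384L)
  lab <- segment_nuclei(core$round1$channels$DAPI, p, core$truth$masks$tissue)
  n <- max(lab)
  expect_lte(abs(n - 400) / 400, 0.02)
  expect_lt(abs(sum(lab > 0) / sum(core$truth$masks$tissue) -
                core$truth$true_fractions$nuclei_fraction), 0.02)
})

test_that("marker positivity stays inside stroma and recovers low FAP levels", {
  fx <- cached_core("mri_pos", side = 320L, seed = 42L, shift = c(7, -4))
  sg <- segment_fixture(fx)
  truth <- fx$core$truth
  epi <- sg$masks$epithelium_objects > 0
  for (mm in sg$masks$marker_masks) {
    expect_equal(sum(mm & epi), 0)
    expect_true(all(!mm | sg$masks$stroma))
  }
  rel_err <- abs(sg$quant$fap_fraction - truth$true_fractions$fap_fraction) /
    truth$true_fractions$fap_fraction
  expect_lt(rel_err, 0.30)
})

test_that("segmentation parameter validation catches bad settings", {
  expect_error(seg_params(adaptive_block_px = 16), ">= 32")
  expect_error(seg_params(min_gland_area_px = 0), ">= 1")
  expect_error(seg_params(nuclei_size_range_px = c(10, 5)), "min < max")
})
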