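# Shared fixtures: generated cores are cached per (class, side, seed, shift)
# so several test files can reuse the same rendering.

.core_cache <- new.env(parent = emptyenv())

cached_core <- function(lesion_class = "mri_pos", side = 320L, seed = 42L,
                        shift = c(0, 0), ...) {
  key <- paste(lesion_class, side, seed, paste(shift, collapse = "_"),
               paste(c(...), collapse = "_"), sep = "|")
  if (is.null(.core_cache[[key]])) {
    spec <- core_spec("fixture", lesion_class, round2_shift = shift,
                      side = side, seed = seed, ...)
    .core_cache[[key]] <- list(spec = spec, core = generate_core(spec))
  }
  .core_cache[[key]]
}

segment_fixture <- function(fx) {
  key <- paste0("seg|", fx$spec$core_id, fx$spec$lesion_class, fx$spec$side,
                fx$spec$seed)
  if (is.null(.core_cache[[key]])) {
    reg <- estimate_shift(fx$core$round1$channels$DAPI,
                          fx$core$round2$channels$DAPI)
    merged <- merge_rounds(fx$core$round1, apply_shift(fx$core$round2,
                                                       reg$shift))
    params <- seg_params_for_side(fx$spec$side)
    masks <- segment_core(merged, params)
    .core_cache[[key]] <- list(reg = reg, masks = masks,
                               quant = quantify_core(masks))
  }
  .core_cache[[key]]
}

# Exhaustive-search Otsu oracle: every possible cut of an integer sample.
otsu_bruteforce <- function(v) {
  lev <- sort(unique(v))
  cuts <- (lev[-1] + lev[-length(lev)]) / 2
  sb <- vapply(cuts, function(ct) {
    lo <- v[v <= ct]; hi <- v[v > ct]
    w0 <- length(lo) / length(v)
    w0 * (1 - w0) * (mean(hi) - mean(lo))^2
  }, numeric(1))
  cuts[which.max(sb)]
}

# Exhaustive integer-shift registration oracle over |dx|,|dy| <= rng.
shift_bruteforce <- function(a, b, rng = 20L) {
  best <- c(-Inf, 0, 0)
  for (dx in -rng:rng) {
    for (dy in -rng:rng) {
      bb <- translate_mat(b, -dx, -dy, fill = NA_real_)
      ok <- !is.na(bb)
      r <- suppressWarnings(cor(a[ok], bb[ok]))
      if (is.finite(r) && r > best[1]) best <- c(r, dx, dy)
    }
  }
  best[2:3]
}
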