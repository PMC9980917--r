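#' Write a multiplexed image as a multi-page TIFF
#'
#' One 16-bit page per channel. Channel names, pixel size and staining round
#' are stored in a plain-text sidecar file (\code{<path>.meta}) so the stack
#' round-trips with [read_multiplex_tiff()].
#'
#' @param image a \code{multiplex_image}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_multiplex_tiff <- function(image, path) {
  pages <- lapply(image$channels, clip01)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  writeLines(c(paste0("channels=", paste(names(image$channels), collapse = ",")),
               paste0("pixel_size_um=", image$pixel_size_um),
               paste0("round=", image$round)),
             paste0(path, ".meta"))
  invisible(path)
}

#' Read a multi-page TIFF written by [write_multiplex_tiff()]
#'
#' @param path TIFF file path; the \code{<path>.meta} sidecar supplies channel
#'   names (pages are named ch1, ch2, ... when it is absent).
#' @param core_id identifier for the returned object.
#' @return a \code{multiplex_image}.
#' @export
read_multiplex_tiff <- function(path, core_id = basename(path)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta")
  meta <- if (file.exists(meta_path)) readLines(meta_path) else character()
  get_field <- function(name, default) {
    m <- grep(paste0("^", name, "="), meta, value = TRUE)
    if (length(m)) sub(paste0("^", name, "="), "", m[1]) else default
  }
  ch_names <- strsplit(get_field("channels", ""), ",")[[1]]
  if (length(ch_names) != length(pages))
    ch_names <- paste0("ch", seq_along(pages))
  channels <- lapply(pages, function(p) {
    m <- as.matrix(p)
    attributes(m) <- list(dim = dim(m))
    m
  })
  names(channels) <- ch_names
  multiplex_image(channels,
                  pixel_size_um = as.numeric(get_field("pixel_size_um", "0.25")),
                  core_id = core_id,
                  round = as.integer(get_field("round", "1")))
}

#' Write label masks as a multi-page 16-bit TIFF
#'
#' @param masks list of integer label matrices or logical masks.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_mask_tiff <- function(masks, path) {
  pages <- lapply(masks, function(m) clip01(unclass(m * 1) / 65535))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  writeLines(paste0("masks=", paste(names(masks), collapse = ",")),
             paste0(path, ".meta"))
  invisible(path)
}
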