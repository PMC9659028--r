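#' Write / read a label mask as 8-bit TIFF
#'
#' Label masks use integer codes 0 (background), 1 (healthy tissue),
#' 2 (ground-truth tumor), 3 (hard negative), stored as an 8-bit
#' single-channel TIFF.
#'
#' @param mask Integer matrix of codes.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(all(mask %in% 0:255))
  img <- mask / 255
  tiff::writeTIFF(img, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write / read a heatmap as 32-bit float TIFF
#'
#' The grid metadata (pixel spacing and slide-frame offset, micrometers) is
#' carried in a JSON sidecar `<path>.json`, since baseline TIFF writers do
#' not expose a metadata tag for physical spacing.
#'
#' @param heatmap A [new_heatmap()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_heatmap_tiff <- function(heatmap, path) {
  tiff::writeTIFF(heatmap$scores, path, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(
    list(spacing_um = heatmap$spacing_um, offset_um = heatmap$offset_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param spacing_um Fallback spacing when the sidecar is missing.
#' @rdname write_heatmap_tiff
#' @export
read_heatmap_tiff <- function(path, spacing_um = NULL) {
  img <- tiff::readTIFF(path)
  offset <- c(0, 0)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    spacing_um <- meta$spacing_um
    offset <- meta$offset_um
  }
  if (is.null(spacing_um)) {
    stop("no spacing metadata for heatmap; pass spacing_um")
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  # float storage can nudge values by rounding
  new_heatmap(pmin(pmax(img, 0), 1), spacing_um, offset)
}

#' Read a cohort manifest CSV
#'
#' @param path Path to a `manifest.csv` written by [generate_cohort()].
#' @return A manifest tibble.
#' @export
read_manifest <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
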