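#' Mine hard-negative regions from a heatmap
#'
#' Implements the single-round hard-negative-mining protocol: threshold an
#' initial model's heatmap at `threshold` (score >= threshold retained),
#' take 8-connected components, keep those strictly larger than ITC size
#' (diameter > `min_diameter_mm`) that have zero pixel overlap with any
#' ground-truth lesion. The retained regions are the benign morphologies the
#' model mistakes for tumor; they are added to the label mask as code 3 and
#' oversampled during retraining.
#'
#' Note the boundary conventions: mining keeps regions with diameter
#' strictly greater than 0.2 mm, whereas detection filtering retains
#' regions of exactly 0.2 mm — both rules are applied literally.
#'
#' @param heatmap A [new_heatmap()].
#' @param annotations Ground-truth annotation tibble with a `polygon`
#'   list-column (micrometers), or `NULL`/empty for a negative slide.
#' @param threshold Score threshold (a pixel at exactly the threshold is
#'   retained), default 0.5.
#' @param min_diameter_mm Minimum diameter, strict, default 0.2.
#' @return Tibble of hard-negative regions: `region_id`, `diameter_mm`,
#'   `n_px`, `score`, centroid coordinates, and a `pixels` list-column of
#'   linear indices into the heatmap grid.
#' @export
mine_hard_negatives <- function(heatmap, annotations = NULL,
                                threshold = 0.5, min_diameter_mm = 0.2) {
  stopifnot(inherits(heatmap, "heatmap_raster"))
  if (is.null(heatmap$spacing_um) || !is.finite(heatmap$spacing_um)) {
    stop("heatmap spacing metadata is required to size regions")
  }
  det <- extract_detections(heatmap, threshold)
  det <- dplyr::filter(det, .data$diameter_mm > min_diameter_mm)
  if (nrow(det) == 0L) return(det)
  if (!is.null(annotations) && nrow(annotations) > 0) {
    gt <- rasterize_polygons(annotations$polygon, dim(heatmap$scores),
                             heatmap$spacing_um)
    gt_idx <- which(gt)
    overlaps <- vapply(det$pixels, function(idx) {
      any(idx %in% gt_idx)
    }, logical(1))
    det <- det[!overlaps, , drop = FALSE]
  }
  det
}

#' Add hard-negative regions to a label mask
#'
#' Sets mined region pixels to code 3 wherever the current code is 1
#' (healthy tissue). Background (0) and ground-truth tumor (2) are never
#' overwritten, so their pixel counts are conserved and the update is
#' idempotent.
#'
#' @param mask Integer label mask with codes in `{0, 1, 2, 3}`.
#' @param regions Regions tibble from [mine_hard_negatives()] (pixel indices
#'   must refer to the same grid as `mask`).
#' @return The updated mask.
#' @export
update_label_mask <- function(mask, regions) {
  stopifnot(all(mask %in% 0:3))
  if (nrow(regions) == 0L) return(mask)
  idx <- unlist(regions$pixels)
  if (any(idx < 1L | idx > length(mask))) {
    stop("region pixels fall outside the mask bounds")
  }
  upd <- idx[mask[idx] == 1L]
  mask[upd] <- 3L
  mask
}
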