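#' Extract detection regions from a heatmap
#'
#' Thresholds the heatmap at `threshold` (pixels with score >= threshold are
#' foreground), labels 8-connected components, and summarizes each component
#' as a detection region with its maximum score, the micrometer coordinate of
#' that maximum (the detection point), and its diameter (major axis of the
#' moment-matched ellipse, millimeters). Coordinates are slide micrometers
#' via the heatmap's spacing and offset.
#'
#' @param heatmap A [new_heatmap()].
#' @param threshold Score threshold, default 0.5 (the project-wide operating
#'   point, shared with hard-negative mining).
#' @return Detections tibble: `region_id`, `score`, `x_um`, `y_um`,
#'   `diameter_mm`, `n_px`, `centroid_x_um`, `centroid_y_um`, plus a
#'   `pixels` list-column of linear indices into the heatmap grid.
#' @export
extract_detections <- function(heatmap, threshold = 0.5) {
  stopifnot(inherits(heatmap, "heatmap_raster"))
  labels <- label_components(heatmap$scores >= threshold)
  props <- region_props(labels, heatmap$spacing_um, scores = heatmap$scores)
  pix <- split(which(labels > 0L), labels[labels > 0L])
  props$pixels <- unname(pix[as.character(props$region_id)])
  props$x_um <- props$x_um + heatmap$offset_um[1]
  props$y_um <- props$y_um + heatmap$offset_um[2]
  props$centroid_x_um <- props$centroid_x_um + heatmap$offset_um[1]
  props$centroid_y_um <- props$centroid_y_um + heatmap$offset_um[2]
  dplyr::select(props, "region_id", "score", "x_um", "y_um", "diameter_mm",
                "n_px", "centroid_x_um", "centroid_y_um", "pixels")
}

#' Remove ITC-sized detections
#'
#' Detections with diameter strictly less than `min_diameter_mm` (default
#' 0.2 mm) most probably correspond to isolated tumor cells and are excluded
#' from evaluation. A detection of exactly 0.2 mm is retained (the exclusion
#' rule is "less than"), even though the TNM label rule still calls that
#' size ITC — the two boundary readings are deliberately kept distinct.
#'
#' @param detections Detections tibble from [extract_detections()].
#' @param min_diameter_mm Exclusion cutoff, millimeters.
#' @return The filtered tibble, order preserved.
#' @export
filter_itc_size <- function(detections, min_diameter_mm = 0.2) {
  dplyr::filter(detections, .data$diameter_mm >= min_diameter_mm)
}

#' Automatic TNM slide label from retained detections
#'
#' Applies the TNM size rules to the largest retained detection: macro for
#' > 2 mm, micro for > 0.2 mm and <= 2 mm, negative otherwise (including the
#' no-detections case and a detection of exactly 0.2 mm, which is ITC-sized).
#'
#' @param detections ITC-filtered detections tibble.
#' @return One of `"negative"`, `"micro"`, `"macro"`.
#' @export
assign_slide_label <- function(detections) {
  if (nrow(detections) == 0L) return("negative")
  tnm_label(max(detections$diameter_mm), itc_as = "negative")
}

#' Slide-level score
#'
#' The slide score is the maximum heatmap value over retained detection
#' regions (the highest-scoring pixel outside sub-0.2 mm regions), or 0 when
#' no region is retained.
#'
#' @param detections ITC-filtered detections tibble.
#' @return A probability in `[0, 1]`.
#' @export
slide_score <- function(detections) {
  if (nrow(detections) == 0L) return(0)
  max(detections$score)
}

#' Full heatmap post-processing for one slide
#'
#' Chains [extract_detections()], [filter_itc_size()], [slide_score()] and
#' [assign_slide_label()] into a slide prediction.
#'
#' @param heatmap A [new_heatmap()].
#' @param slide_id Identifier carried into the result.
#' @param threshold Detection threshold.
#' @param min_diameter_mm ITC size cutoff.
#' @return List with `slide_id`, `detections` (retained), `slide_score`,
#'   `predicted_label`.
#' @export
predict_slide_label <- function(heatmap, slide_id = NA_character_,
                                threshold = 0.5, min_diameter_mm = 0.2) {
  det <- filter_itc_size(extract_detections(heatmap, threshold),
                         min_diameter_mm)
  list(slide_id = slide_id, detections = det,
       slide_score = slide_score(det),
       predicted_label = assign_slide_label(det))
}

#' Export detection regions as ASAP-dialect XML
#'
#' Each region's outline (convex hull of its pixel centers in slide
#' micrometers) becomes one polygon annotation, reviewable in a slide
#' viewer and round-trippable through [read_asap_xml()].
#'
#' @param detections Detections tibble with a `pixels` list-column.
#' @param heatmap The source heatmap (for spacing/offset).
#' @param path Output file.
#' @param slide_id Used in annotation names.
#' @return `path`, invisibly.
#' @export
export_asap_xml <- function(detections, heatmap, path,
                            slide_id = "slide") {
  h <- nrow(heatmap$scores)
  polys <- lapply(detections$pixels, function(idx) {
    ri <- ((idx - 1L) %% h) + 1L
    ci <- ((idx - 1L) %/% h) + 1L
    x <- heatmap$offset_um[1] + (ci - 0.5) * heatmap$spacing_um
    y <- heatmap$offset_um[2] + (ri - 0.5) * heatmap$spacing_um
    hull <- grDevices::chull(x, y)
    cbind(x = x[hull], y = y[hull])
  })
  nm <- sprintf("%s_detection_%d", slide_id,
                seq_len(nrow(detections)))
  write_asap_xml(polys, path, names = nm, group = "detections")
}
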