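#' TNM slide label from a metastasis diameter
#'
#' Applies the WHO TNM size rules for nodal breast-cancer deposits:
#' macro-metastasis for tumor > 2 mm, micro-metastasis for > 0.2 mm and
#' <= 2 mm, isolated tumor cells (ITC, slide-negative) for <= 0.2 mm.
#'
#' @param diameter_mm Numeric vector of deposit diameters in millimeters;
#'   `NA` or values <= 0 mean no deposit.
#' @param itc_as Label to return for the ITC size class: `"itc_only"` keeps
#'   the ITC class visible (ground-truth labeling), `"negative"` collapses it
#'   to slide-negative (automatic prediction labeling, where sub-0.2 mm
#'   detections have already been filtered out).
#' @return Character vector of labels in
#'   `{"negative", "micro", "macro", "itc_only"}`.
#' @export
tnm_label <- function(diameter_mm, itc_as = c("itc_only", "negative")) {
  itc_as <- match.arg(itc_as)
  out <- rep("negative", length(diameter_mm))
  d <- diameter_mm
  has <- !is.na(d) & d > 0
  out[has & d <= 0.2] <- itc_as
  out[has & d > 0.2 & d <= 2] <- "micro"
  out[has & d > 2] <- "macro"
  out
}

#' Is a slide label positive under TNM?
#'
#' ITC-only and negative slides are node-negative; micro- and
#' macro-metastases are positive. `"positive"` is accepted as a coarse label
#' for study manifests where the micro/macro breakdown is not recorded.
#'
#' @param gt_label Character vector of slide labels.
#' @return Logical vector.
#' @export
is_positive_label <- function(gt_label) {
  gt_label %in% c("micro", "macro", "positive")
}
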