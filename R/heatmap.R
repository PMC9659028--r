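#' Construct a tumor-probability heatmap
#'
#' A heatmap is a per-position tumor-probability raster produced either by
#' applying a classifier fully convolutionally to a slide or by the synthetic
#' generator. Values live in `[0, 1]`; `spacing_um` is the micrometer pitch of
#' the heatmap grid and `offset_um` the slide-frame coordinate of the grid
#' origin (top-left corner of the first pixel).
#'
#' @param scores Numeric matrix in `[0, 1]` (rows = y, cols = x).
#' @param spacing_um Micrometers per heatmap pixel.
#' @param offset_um Length-2 numeric, `(x, y)` offset of the grid origin in
#'   slide micrometers.
#' @return An object of class `heatmap_raster`.
#' @export
new_heatmap <- function(scores, spacing_um, offset_um = c(0, 0)) {
  stopifnot(is.matrix(scores), spacing_um > 0, length(offset_um) == 2)
  if (anyNA(scores) || min(scores) < 0 || max(scores) > 1) {
    stop("heatmap scores must be in [0, 1]")
  }
  structure(
    list(scores = scores, spacing_um = spacing_um,
         offset_um = as.numeric(offset_um)),
    class = "heatmap_raster"
  )
}

#' @export
print.heatmap_raster <- function(x, ...) {
  cat(sprintf(
    "<heatmap_raster> %d x %d px @ %.3g um/px, offset (%.1f, %.1f) um, range [%.3f, %.3f]\n",
    nrow(x$scores), ncol(x$scores), x$spacing_um,
    x$offset_um[1], x$offset_um[2], min(x$scores), max(x$scores)))
  invisible(x)
}

#' @export
dim.heatmap_raster <- function(x) dim(x$scores)

#' Plot a heatmap raster
#'
#' @param object A `heatmap_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot heatmap_raster
#' @export
autoplot.heatmap_raster <- function(object, ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object$scores)),
    col = seq_len(ncol(object$scores))
  )
  df$score <- as.vector(t(object$scores))
  df$x_um <- object$offset_um[1] + (df$col - 0.5) * object$spacing_um
  df$y_um <- object$offset_um[2] + (df$row - 0.5) * object$spacing_um
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  fill = "tumor\nprobability")
}
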