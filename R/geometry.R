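#' Label connected components of a logical raster
#'
#' Labels the `TRUE` pixels of a binary raster into connected components.
#' The project-wide convention is 8-connectivity (diagonally touching pixels
#' belong to the same component), matching how metastasis regions and
#' hard-negative regions are delineated throughout the package.
#'
#' @param mask Logical matrix (rows = y, columns = x).
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of the same dimension; 0 for background, components
#'   numbered from 1 in raster scan order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  mode(mask) <- "logical"
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  fg <- which(mask)
  if (length(fg) == 0L) return(out)

  row_of <- ((fg - 1L) %% h) + 1L
  col_of <- ((fg - 1L) %/% h) + 1L

  # neighbor offsets in linear-index space (column-major): down, right, and
  # the two diagonals for 8-connectivity; boundary rows/cols excluded per offset
  offs <- list(
    list(d = 1L,      ok = row_of < h),                 # down
    list(d = h,       ok = col_of < w)                  # right
  )
  if (connectivity == 8L) {
    offs <- c(offs, list(
      list(d = h + 1L, ok = row_of < h & col_of < w),   # down-right
      list(d = h - 1L, ok = row_of > 1L & col_of < w)   # up-right
    ))
  }

  inmask <- logical(h * w)
  inmask[fg] <- TRUE
  edges <- lapply(offs, function(o) {
    a <- fg[o$ok]
    b <- a + o$d
    keep <- inmask[b]
    cbind(a[keep], b[keep])
  })
  edges <- do.call(rbind, edges)

  # map pixel linear indices to 1..n vertex ids
  vid <- integer(h * w)
  vid[fg] <- seq_along(fg)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, rbind(vid[edges[, 1L]], vid[edges[, 2L]]))
  }
  comp <- igraph::components(g)$membership

  # renumber components by first occurrence in raster scan (row-major) order
  scan_order <- order(row_of, col_of)
  first_seen <- !duplicated(comp[scan_order])
  relabel <- integer(max(comp))
  relabel[comp[scan_order][first_seen]] <- seq_len(sum(first_seen))
  out[fg] <- relabel[comp]
  out
}

#' Measure labeled regions
#'
#' Computes per-region size, centroid, score statistics and the diameter used
#' for TNM-style sizing. The diameter is the major-axis length of the
#' region's best-fit (moment-matched) ellipse, scaled to millimeters: for a
#' region with pixel-center covariance matrix `S`, the major axis is
#' `4 * sqrt(max eigenvalue of S)` pixels, which equals the true diameter for
#' a filled disc or ellipse. This is the long-axis convention pathologists use
#' when sizing metastases.
#'
#' @param labels Integer label matrix from [label_components()].
#' @param spacing_um Pixel spacing of the raster, micrometers per pixel.
#' @param scores Optional numeric matrix (same dim) of per-pixel scores; when
#'   given, each region's maximum score and argmax location are reported.
#' @return A tibble with one row per region: `region_id`, `n_px`,
#'   `centroid_x_um`, `centroid_y_um`, `diameter_mm`, and when scores are
#'   supplied `score`, `x_um`, `y_um` (location of the region's score maximum,
#'   micrometer coordinates of the pixel center).
#' @export
region_props <- function(labels, spacing_um, scores = NULL) {
  stopifnot(is.matrix(labels), spacing_um > 0)
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(
      region_id = integer(), n_px = integer(),
      centroid_x_um = double(), centroid_y_um = double(),
      diameter_mm = double(),
      score = double(), x_um = double(), y_um = double()
    ))
  }
  h <- nrow(labels)
  lab <- labels[idx]
  ri <- ((idx - 1L) %% h) + 1L
  ci <- ((idx - 1L) %/% h) + 1L
  # pixel centers in micrometers, origin at the raster's top-left corner
  x <- (ci - 0.5) * spacing_um
  y <- (ri - 0.5) * spacing_um

  split_i <- split(seq_along(idx), lab)
  props <- lapply(split_i, function(ii) {
    xs <- x[ii]; ys <- y[ii]; n <- length(ii)
    mx <- mean(xs); my <- mean(ys)
    # population second moments of pixel centers
    cxx <- mean((xs - mx)^2); cyy <- mean((ys - my)^2)
    cxy <- mean((xs - mx) * (ys - my))
    tr <- cxx + cyy
    det <- cxx * cyy - cxy^2
    lam <- max((tr + sqrt(max(tr^2 - 4 * det, 0))) / 2, 0)  # largest eigenvalue
    d_um <- 4 * sqrt(lam)
    out <- list(n_px = n, centroid_x_um = mx, centroid_y_um = my,
                diameter_mm = d_um / 1000)
    if (!is.null(scores)) {
      sc <- scores[idx[ii]]
      top <- which(sc == max(sc))
      # tie-break toward the centroid so flat-topped regions yield an
      # interior detection point
      k <- top[which.min((xs[top] - mx)^2 + (ys[top] - my)^2)]
      out$score <- sc[k]
      out$x_um <- xs[k]
      out$y_um <- ys[k]
    }
    out
  })
  res <- dplyr::bind_rows(props)
  res <- dplyr::mutate(res, region_id = as.integer(names(split_i)),
                       .before = 1L)
  dplyr::arrange(res, .data$region_id)
}

#' Vertices of an ellipse as a closed polygon
#'
#' @param cx,cy Center, micrometers.
#' @param major_um,minor_um Full axis lengths (not semi-axes), micrometers.
#' @param angle Rotation of the major axis, radians.
#' @param n Number of vertices.
#' @return Two-column matrix of (x, y) vertices, closed (first == last).
#' @export
ellipse_polygon <- function(cx, cy, major_um, minor_um, angle = 0, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1)
  a <- major_um / 2; b <- minor_um / 2
  x0 <- a * cos(t); y0 <- b * sin(t)
  cbind(x = cx + x0 * cos(angle) - y0 * sin(angle),
        y = cy + x0 * sin(angle) + y0 * cos(angle))
}

#' Rasterize a set of ellipses into a logical mask
#'
#' Pixels whose centers fall inside any ellipse are set `TRUE`. Works from
#' the analytic ellipse equation, so the raster is exact at pixel-center
#' resolution.
#'
#' @param ellipses Data frame with columns `cx_um`, `cy_um`, `major_um`,
#'   `minor_um`, `angle` (radians).
#' @param extent_px `c(rows, cols)` of the target raster.
#' @param spacing_um Micrometers per pixel.
#' @return Logical matrix.
#' @export
rasterize_ellipses <- function(ellipses, extent_px, spacing_um) {
  mask <- matrix(FALSE, extent_px[1], extent_px[2])
  if (is.null(ellipses) || nrow(ellipses) == 0L) return(mask)
  for (k in seq_len(nrow(ellipses))) {
    mask[ellipse_indices(ellipses[k, ], extent_px, spacing_um)] <- TRUE
  }
  mask
}

#' Linear indices of pixels inside one ellipse
#'
#' Bounding-box-limited rasterization of a single ellipse; pixel centers
#' inside the analytic ellipse are returned as linear (column-major) indices
#' into a raster of the given extent.
#'
#' @param e One-row data frame with `cx_um`, `cy_um`, `major_um`, `minor_um`,
#'   `angle`.
#' @param extent_px `c(rows, cols)`.
#' @param spacing_um Micrometers per pixel.
#' @return Integer vector of linear indices.
#' @export
ellipse_indices <- function(e, extent_px, spacing_um) {
  a <- e$major_um / 2; b <- e$minor_um / 2
  r0 <- max(1L, floor((e$cy_um - a) / spacing_um))
  r1 <- min(extent_px[1], ceiling((e$cy_um + a) / spacing_um) + 1L)
  c0 <- max(1L, floor((e$cx_um - a) / spacing_um))
  c1 <- min(extent_px[2], ceiling((e$cx_um + a) / spacing_um) + 1L)
  if (r0 > r1 || c0 > c1) return(integer())
  rows <- r0:r1; cols <- c0:c1
  yy <- (rows - 0.5) * spacing_um - e$cy_um
  xx <- (cols - 0.5) * spacing_um - e$cx_um
  ca <- cos(e$angle); sa <- sin(e$angle)
  X <- matrix(xx, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(yy, length(rows), length(cols))
  u <- X * ca + Y * sa
  v <- -X * sa + Y * ca
  inside <- which((u / a)^2 + (v / b)^2 <= 1)
  ri <- rows[((inside - 1L) %% length(rows)) + 1L]
  ci <- cols[((inside - 1L) %/% length(rows)) + 1L]
  ri + (ci - 1L) * extent_px[1]
}

#' Rasterize closed polygons into a logical mask
#'
#' @param polygons List of two-column (x, y) vertex matrices in micrometers.
#' @param extent_px `c(rows, cols)`.
#' @param spacing_um Micrometers per pixel.
#' @return Logical matrix; pixels whose centers fall inside any polygon.
#' @export
rasterize_polygons <- function(polygons, extent_px, spacing_um) {
  mask <- matrix(FALSE, extent_px[1], extent_px[2])
  for (poly in polygons) {
    mask[polygon_indices(poly, extent_px, spacing_um)] <- TRUE
  }
  mask
}

#' Linear indices of pixels inside one polygon
#'
#' @param poly Two-column (x, y) vertex matrix in micrometers.
#' @param extent_px `c(rows, cols)`.
#' @param spacing_um Micrometers per pixel.
#' @return Integer vector of linear (column-major) indices whose pixel
#'   centers fall inside the polygon.
#' @export
polygon_indices <- function(poly, extent_px, spacing_um) {
  r0 <- max(1L, floor(min(poly[, 2]) / spacing_um))
  r1 <- min(extent_px[1], ceiling(max(poly[, 2]) / spacing_um) + 1L)
  c0 <- max(1L, floor(min(poly[, 1]) / spacing_um))
  c1 <- min(extent_px[2], ceiling(max(poly[, 1]) / spacing_um) + 1L)
  if (r0 > r1 || c0 > c1) return(integer())
  rows <- r0:r1; cols <- c0:c1
  pts <- cbind(rep((cols - 0.5) * spacing_um, each = length(rows)),
               rep((rows - 0.5) * spacing_um, times = length(cols)))
  inside <- which(mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), pts))
  ri <- rows[((inside - 1L) %% length(rows)) + 1L]
  ci <- cols[((inside - 1L) %/% length(rows)) + 1L]
  ri + (ci - 1L) * extent_px[1]
}

#' Test points against a list of polygons
#'
#' @param x_um,y_um Point coordinates, micrometers.
#' @param polygons List of two-column vertex matrices.
#' @return Integer vector: index of the first polygon containing each point,
#'   or `NA` if none does.
#' @export
points_in_polygons <- function(x_um, y_um, polygons) {
  hit <- rep(NA_integer_, length(x_um))
  if (length(x_um) == 0L || length(polygons) == 0L) return(hit)
  pts <- cbind(x_um, y_um)
  for (k in seq_along(polygons)) {
    poly <- polygons[[k]]
    todo <- is.na(hit)
    if (!any(todo)) break
    inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
                           pts[todo, , drop = FALSE])
    hit[which(todo)[inside]] <- k
  }
  hit
}
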