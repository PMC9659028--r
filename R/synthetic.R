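#' Specification of a synthetic slide cohort
#'
#' Describes one synthetic dataset: how many metastasis-free and
#' metastasis-bearing slides to generate, how many lesions a positive slide
#' carries, the mix of micro- (0.2--2 mm) and macro- (> 2 mm) metastases, the
#' fraction of "positive" slides that in fact carry only ITC-sized deposits
#' (<= 0.2 mm, node-negative under TNM), and the slide geometry.
#'
#' Lesion diameters are sampled uniformly from per-class ranges. The default
#' ranges keep a small guard band away from the 0.2 mm and 2 mm TNM
#' boundaries so that the planted size class survives rasterization at the
#' working raster spacing and the planted truth stays analytically known.
#'
#' @param dataset_name Dataset label written into slide ids and the manifest.
#' @param n_negative,n_positive Slide counts (non-negative).
#' @param lesions_per_positive Integer range `c(min, max)` of lesions planted
#'   on a positive slide.
#' @param micro_fraction Probability that a planted lesion is a
#'   micro-metastasis rather than a macro-metastasis.
#' @param itc_fraction Probability that a nominally positive slide carries
#'   only ITC-sized lesions (its ground-truth label becomes `"itc_only"`).
#' @param confounder_rate Expected number of benign confounder texture spots
#'   per slide (Poisson); these perturb the tissue raster only and carry no
#'   annotation.
#' @param slide_extent_mm Slide width/height in millimeters.
#' @param pixel_spacing_um Level-0 pixel spacing recorded in the manifest
#'   (the spacing at which patches are read), micrometers per pixel.
#' @param raster_spacing_um Working spacing of the generated tissue raster,
#'   label mask and heatmap grid, micrometers per pixel.
#' @param micro_range_mm,macro_range_mm,itc_range_mm Uniform sampling ranges
#'   for lesion diameters per size class, millimeters.
#' @param procedure Surgical procedure recorded in the manifest.
#' @param seed Integer seed; every slide is a pure function of
#'   `(seed, slide_index)`.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(dataset_name = "Synthetic",
                        n_negative = 10, n_positive = 10,
                        lesions_per_positive = c(1L, 3L),
                        micro_fraction = 0.6,
                        itc_fraction = 0,
                        confounder_rate = 0,
                        slide_extent_mm = 20,
                        pixel_spacing_um = 0.5,
                        raster_spacing_um = 16,
                        micro_range_mm = c(0.3, 2),
                        macro_range_mm = c(2.5, 8),
                        itc_range_mm = c(0.05, 0.18),
                        procedure = "sentinel",
                        seed = 1L) {
  stopifnot(
    n_negative >= 0, n_positive >= 0,
    length(lesions_per_positive) == 2, lesions_per_positive[1] >= 1,
    diff(lesions_per_positive) >= 0,
    micro_fraction >= 0, micro_fraction <= 1,
    itc_fraction >= 0, itc_fraction <= 1,
    confounder_rate >= 0,
    slide_extent_mm > 0, pixel_spacing_um > 0, raster_spacing_um > 0,
    diff(micro_range_mm) >= 0, diff(macro_range_mm) >= 0,
    diff(itc_range_mm) >= 0
  )
  largest <- if (micro_fraction < 1) macro_range_mm[2] else micro_range_mm[2]
  if (n_positive > 0 && largest > 0.5 * slide_extent_mm) {
    stop(sprintf(
      "slide extent %.3g mm cannot hold lesions up to %.3g mm diameter",
      slide_extent_mm, largest))
  }
  structure(
    list(dataset_name = dataset_name, n_negative = as.integer(n_negative),
         n_positive = as.integer(n_positive),
         lesions_per_positive = as.integer(lesions_per_positive),
         micro_fraction = micro_fraction, itc_fraction = itc_fraction,
         confounder_rate = confounder_rate,
         slide_extent_mm = slide_extent_mm,
         pixel_spacing_um = pixel_spacing_um,
         raster_spacing_um = raster_spacing_um,
         micro_range_mm = micro_range_mm, macro_range_mm = macro_range_mm,
         itc_range_mm = itc_range_mm,
         procedure = procedure, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Specification of synthetic heatmap generation
#'
#' Controls the score distributions of a model-like tumor-probability
#' heatmap: scores inside true lesions, background scores, and
#' benign-confounder false-positive blobs planted at a Poisson per-slide
#' rate. Presets of 35 and 1.3 blobs per slide emulate the false-positive
#' burden of an unadapted and a locally retrained detector, respectively.
#'
#' Score distributions are clipped normals parameterized by
#' `c(location, spread)`; a spread of 0 gives a constant score.
#'
#' @param in_lesion_score c(location, spread) of per-pixel scores inside
#'   ground-truth lesions.
#' @param background_score c(location, spread) of background scores.
#' @param fp_blob_rate Expected false-positive blobs per slide (Poisson).
#' @param fp_blob_diameter_range_mm Uniform range of blob diameters. The
#'   default stays above the 0.2 mm ITC filter so every planted blob
#'   survives detection post-processing.
#' @param fp_blob_score c(location, spread) of the single score each blob is
#'   filled with.
#' @param seed Integer seed.
#' @return A `heatmap_spec` list.
#' @export
heatmap_spec <- function(in_lesion_score = c(0.95, 0.02),
                         background_score = c(0.05, 0.02),
                         fp_blob_rate = 0,
                         fp_blob_diameter_range_mm = c(0.25, 1.0),
                         fp_blob_score = c(0.75, 0.08),
                         seed = 1L) {
  stopifnot(
    fp_blob_rate >= 0,
    length(fp_blob_diameter_range_mm) == 2,
    fp_blob_diameter_range_mm[1] > 0,
    diff(fp_blob_diameter_range_mm) >= 0,
    in_lesion_score[2] >= 0, background_score[2] >= 0, fp_blob_score[2] >= 0
  )
  structure(
    list(in_lesion_score = in_lesion_score,
         background_score = background_score,
         fp_blob_rate = fp_blob_rate,
         fp_blob_diameter_range_mm = fp_blob_diameter_range_mm,
         fp_blob_score = fp_blob_score, seed = as.integer(seed)),
    class = "heatmap_spec"
  )
}

# draw n values from a clipped normal given c(location, spread)
draw_scores <- function(n, dist) {
  if (n == 0L) return(numeric())
  if (dist[2] == 0) return(rep(dist[1], n))
  pmin(pmax(stats::rnorm(n, dist[1], dist[2]), 0), 1)
}

# rejection-sample non-overlapping ellipse centers inside the tissue region;
# `clear_mm` is the minimum boundary-to-boundary clearance (upper-bounded via
# major axes) so rasterized regions never merge under 8-connectivity
place_ellipses <- function(diameters_mm, extent_um, tissue_frac = 0.85,
                           existing = NULL, clear_mm = 0.05,
                           max_tries = 2000L, on_fail = c("error", "skip")) {
  on_fail <- match.arg(on_fail)
  placed <- existing
  out <- vector("list", length(diameters_mm))
  for (k in seq_along(diameters_mm)) {
    d_um <- diameters_mm[k] * 1000
    a <- d_um / 2
    # tissue is a centered ellipse with axes tissue_frac * extent; keep the
    # lesion center inside the tissue ellipse shrunk by the lesion radius
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, a, extent_um[1] - a)
      cy <- stats::runif(1, a, extent_um[2] - a)
      ex <- (cx - extent_um[1] / 2) / (tissue_frac * extent_um[1] / 2 - a)
      ey <- (cy - extent_um[2] / 2) / (tissue_frac * extent_um[2] / 2 - a)
      if (!is.finite(ex) || !is.finite(ey) || ex^2 + ey^2 > 1) next
      clash <- FALSE
      if (!is.null(placed) && nrow(placed) > 0) {
        dist <- sqrt((placed$cx_um - cx)^2 + (placed$cy_um - cy)^2)
        clash <- any(dist < (placed$major_um + d_um) / 2 + clear_mm * 1000)
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) {
      if (on_fail == "skip") next
      stop(sprintf(
        "could not place a %.3g mm region in a %.3g mm slide; extent too small",
        diameters_mm[k], extent_um[1] / 1000))
    }
    row <- tibble::tibble(
      cx_um = cx, cy_um = cy, major_um = d_um,
      minor_um = d_um * stats::runif(1, 0.65, 1),
      angle = stats::runif(1, 0, pi)
    )
    placed <- dplyr::bind_rows(placed, row)
    out[[k]] <- row
  }
  dplyr::bind_rows(out)
}

# centered-ellipse tissue mask plus a smooth low-entropy intensity texture
make_tissue_raster <- function(extent_px, spacing_um, tissue_frac = 0.8,
                               n_confounders = 0L) {
  ell <- tibble::tibble(
    cx_um = extent_px[2] * spacing_um / 2,
    cy_um = extent_px[1] * spacing_um / 2,
    major_um = tissue_frac * extent_px[2] * spacing_um,
    minor_um = tissue_frac * extent_px[1] * spacing_um,
    angle = 0
  )
  tissue <- rasterize_ellipses(ell, extent_px, spacing_um)
  # smooth texture: sum of a few random low-frequency cosines
  rows <- matrix(seq_len(extent_px[1]), extent_px[1], extent_px[2])
  cols <- matrix(seq_len(extent_px[2]), extent_px[1], extent_px[2],
                 byrow = TRUE)
  tex <- matrix(0, extent_px[1], extent_px[2])
  for (k in 1:3) {
    fr <- stats::runif(2, 0.5, 3) * 2 * pi / max(extent_px)
    ph <- stats::runif(2, 0, 2 * pi)
    tex <- tex + cos(rows * fr[1] + ph[1]) * cos(cols * fr[2] + ph[2])
  }
  intensity <- 0.55 + 0.1 * tex / 3
  if (n_confounders > 0L) {
    diam <- stats::runif(n_confounders, 0.3, 1.5)
    spots <- try(place_ellipses(diam, rev(extent_px) * spacing_um),
                 silent = TRUE)
    if (!inherits(spots, "try-error")) {
      spot_mask <- rasterize_ellipses(spots, extent_px, spacing_um)
      intensity[spot_mask] <- intensity[spot_mask] - 0.15
    }
  }
  intensity[!tissue] <- 0
  list(intensity = pmin(pmax(intensity, 0), 1), tissue = tissue,
       spacing_um = spacing_um)
}

#' Generate one synthetic slide
#'
#' Builds the tissue raster, the ground-truth lesion annotations and the
#' slide record for slide `slide_index` of a cohort. Slides
#' `1..n_negative` are metastasis-free; the remainder carry 1 or more planted
#' elliptical lesions whose major-axis diameters follow the cohort
#' specification. The
#' slide's ground-truth label is the TNM rule applied to the largest planted
#' diameter. Deterministic given `(spec$seed, slide_index)`.
#'
#' @param spec A [cohort_spec()].
#' @param slide_index 1-based slide index, at most `n_negative + n_positive`.
#' @return A list with `raster` (intensity + tissue mask), `annotations`
#'   (tibble: `lesion_id`, ellipse geometry, `diameter_mm`, `size_class`,
#'   `polygon` list-column in slide micrometers), and `record` (one manifest
#'   row).
#' @export
generate_slide <- function(spec, slide_index) {
  stopifnot(inherits(spec, "cohort_spec"),
            slide_index >= 1,
            slide_index <= spec$n_negative + spec$n_positive)
  extent_um <- rep(spec$slide_extent_mm * 1000, 2)
  extent_px <- rep(as.integer(round(spec$slide_extent_mm * 1000 /
                                      spec$raster_spacing_um)), 2)
  positive <- slide_index > spec$n_negative

  with_seed(derive_seed(spec$seed, slide_index), {
    annotations <- tibble::tibble(
      lesion_id = integer(), cx_um = double(), cy_um = double(),
      major_um = double(), minor_um = double(), angle = double(),
      diameter_mm = double(), size_class = character(), polygon = list()
    )
    if (positive) {
      n_lesions <- sample.int(spec$lesions_per_positive[2] -
                                spec$lesions_per_positive[1] + 1L, 1L) +
        spec$lesions_per_positive[1] - 1L
      itc_slide <- stats::runif(1) < spec$itc_fraction
      size_class <- if (itc_slide) rep("itc", n_lesions) else {
        ifelse(stats::runif(n_lesions) < spec$micro_fraction, "micro", "macro")
      }
      rng_of <- list(itc = spec$itc_range_mm, micro = spec$micro_range_mm,
                     macro = spec$macro_range_mm)
      # multi-lesion layouts can be geometrically infeasible for extreme
      # diameter draws; redraw diameters (same distribution) a few times,
      # placing largest-first, before giving up with a sizing error
      geom <- NULL
      for (attempt in 1:50) {
        diameters <- vapply(size_class, function(cl) {
          r <- rng_of[[cl]]; stats::runif(1, r[1], r[2])
        }, numeric(1))
        ord <- order(diameters, decreasing = TRUE)
        g <- try(place_ellipses(diameters[ord], extent_um, clear_mm = 0.15),
                 silent = TRUE)
        if (!inherits(g, "try-error")) {
          geom <- g[order(ord), , drop = FALSE]
          break
        }
      }
      if (is.null(geom)) {
        stop(sprintf(
          "cannot fit %d lesions (classes: %s) in a %.3g mm slide",
          n_lesions, paste(size_class, collapse = ","), spec$slide_extent_mm))
      }
      annotations <- dplyr::bind_cols(
        tibble::tibble(lesion_id = seq_len(n_lesions)), geom,
        tibble::tibble(diameter_mm = diameters, size_class = size_class)
      )
      annotations$polygon <- purrr::pmap(
        geom, function(cx_um, cy_um, major_um, minor_um, angle) {
          ellipse_polygon(cx_um, cy_um, major_um, minor_um, angle)
        })
    }
    n_conf <- stats::rpois(1, spec$confounder_rate)
    raster <- make_tissue_raster(extent_px, spec$raster_spacing_um,
                                 n_confounders = n_conf)
    gt <- if (nrow(annotations) == 0) "negative" else {
      tnm_label(max(annotations$diameter_mm))
    }
    record <- tibble::tibble(
      slide_id = sprintf("%s_%04d", spec$dataset_name, slide_index),
      dataset = spec$dataset_name,
      procedure = spec$procedure,
      subtype = "unknown",
      gt_label = gt,
      split = "unassigned",
      annotation_status = if (nrow(annotations)) "full" else "none",
      enrichment = FALSE,
      spacing_um = spec$pixel_spacing_um,
      raster_spacing_um = spec$raster_spacing_um,
      n_lesions = nrow(annotations)
    )
    list(raster = raster, annotations = annotations, record = record)
  })
}

#' Rasterize a label mask from annotations
#'
#' Produces the training label mask: 0 background, 1 healthy tissue, 2
#' ground-truth tumor (hard negatives, code 3, are added later by mining).
#'
#' @param annotations Annotation tibble from [generate_slide()].
#' @param tissue Logical tissue mask.
#' @param spacing_um Raster spacing, micrometers per pixel.
#' @return Integer matrix of codes `{0, 1, 2}`.
#' @export
label_mask <- function(annotations, tissue, spacing_um) {
  mask <- matrix(0L, nrow(tissue), ncol(tissue))
  mask[tissue] <- 1L
  if (!is.null(annotations) && nrow(annotations) > 0) {
    tumor <- rasterize_polygons(annotations$polygon, dim(tissue), spacing_um)
    mask[tumor] <- 2L
  }
  mask
}

#' Generate a model-like heatmap for one slide
#'
#' Fills lesion interiors with draws from the in-lesion score distribution,
#' the rest of the grid with background draws, and plants
#' `Poisson(fp_blob_rate)` benign-confounder blobs outside all lesions, each
#' filled with a single score from the blob score distribution. Blobs are
#' rejection-sampled so they never touch a lesion or each other, keeping the
#' planted detection count analytically known. Deterministic given
#' `hspec$seed` (mix in a slide index via `seed_index` for per-slide
#' streams).
#'
#' @param annotations Annotation tibble (possibly empty).
#' @param hspec A [heatmap_spec()].
#' @param extent_px `c(rows, cols)` of the heatmap grid.
#' @param spacing_um Heatmap spacing, micrometers per pixel.
#' @param seed_index Extra integer mixed into the seed (e.g. slide index).
#' @return A [new_heatmap()] with attribute `"planted"`: a tibble of planted
#'   regions (`type` = `"lesion"`/`"fp_blob"`, geometry, `score`,
#'   `diameter_mm`).
#' @export
generate_heatmap <- function(annotations, hspec, extent_px, spacing_um,
                             seed_index = 0L) {
  stopifnot(inherits(hspec, "heatmap_spec"))
  with_seed(derive_seed(hspec$seed, 7L, seed_index), {
    scores <- matrix(draw_scores(prod(extent_px), hspec$background_score),
                     extent_px[1], extent_px[2])
    planted <- tibble::tibble(
      type = character(), cx_um = double(), cy_um = double(),
      diameter_mm = double(), score = double()
    )
    lesion_geom <- NULL
    if (!is.null(annotations) && nrow(annotations) > 0) {
      lesion_geom <- annotations[, c("cx_um", "cy_um", "major_um",
                                     "minor_um", "angle")]
      for (k in seq_len(nrow(annotations))) {
        # rasterize from the annotation polygon (not the analytic ellipse)
        # so every in-lesion pixel center lies inside the exported polygon
        idx <- polygon_indices(annotations$polygon[[k]], extent_px,
                               spacing_um)
        scores[idx] <- draw_scores(length(idx), hspec$in_lesion_score)
        planted <- dplyr::bind_rows(planted, tibble::tibble(
          type = "lesion", cx_um = annotations$cx_um[k],
          cy_um = annotations$cy_um[k],
          diameter_mm = annotations$diameter_mm[k],
          score = if (length(idx)) max(scores[idx]) else NA_real_
        ))
      }
    }
    n_blobs <- stats::rpois(1, hspec$fp_blob_rate)
    if (n_blobs > 0) {
      diam <- stats::runif(n_blobs, hspec$fp_blob_diameter_range_mm[1],
                           hspec$fp_blob_diameter_range_mm[2])
      # a blob that cannot be placed (crowded small raster) is dropped, so
      # the planted table always matches what is actually in the heatmap
      blobs <- place_ellipses(diam, rev(extent_px) * spacing_um,
                              existing = lesion_geom, on_fail = "skip")
      n_blobs <- nrow(blobs)
      blob_scores <- draw_scores(n_blobs, hspec$fp_blob_score)
      diam <- blobs$major_um / 1000
      for (k in seq_len(n_blobs)) {
        idx <- ellipse_indices(blobs[k, ], extent_px, spacing_um)
        scores[idx] <- pmax(scores[idx], blob_scores[k])
        planted <- dplyr::bind_rows(planted, tibble::tibble(
          type = "fp_blob", cx_um = blobs$cx_um[k], cy_um = blobs$cy_um[k],
          diameter_mm = diam[k], score = blob_scores[k]
        ))
      }
    }
    hm <- new_heatmap(scores, spacing_um)
    attr(hm, "planted") <- planted
    hm
  })
}

#' Generate a full synthetic cohort on disk
#'
#' Runs [generate_slide()] and [generate_heatmap()] for every slide of every
#' spec and writes the assets a study run consumes: `manifest.csv`,
#' ASAP-dialect annotation XML per positive slide, uint8 label-mask TIFFs,
#' float32 heatmap TIFFs, and `planted.csv` with the generator's planted
#' truth. Two runs with the same seeds produce byte-identical manifests.
#'
#' @param specs A [cohort_spec()] or list of them (unique dataset names).
#' @param hspec A [heatmap_spec()].
#' @param output_dir Directory to create.
#' @param overwrite Overwrite an existing non-empty directory?
#' @param write_heatmaps,write_masks Toggle the large raster assets.
#' @return The manifest tibble (invisibly written to `manifest.csv`), with
#'   per-slide asset paths.
#' @export
generate_cohort <- function(specs, hspec = heatmap_spec(), output_dir,
                            overwrite = FALSE, write_heatmaps = TRUE,
                            write_masks = TRUE) {
  if (inherits(specs, "cohort_spec")) specs <- list(specs)
  nm <- vapply(specs, function(s) s$dataset_name, character(1))
  if (anyDuplicated(nm)) stop("dataset names must be unique")
  if (dir.exists(output_dir) && length(dir(output_dir)) > 0 && !overwrite) {
    stop("output_dir exists and is not empty; use overwrite = TRUE")
  }
  for (d in c("", "annotations", "masks", "heatmaps")) {
    dir.create(file.path(output_dir, d), recursive = TRUE,
               showWarnings = FALSE)
  }
  records <- list(); planted_all <- list()
  for (spec in specs) {
    n <- spec$n_negative + spec$n_positive
    for (i in seq_len(n)) {
      sl <- generate_slide(spec, i)
      id <- sl$record$slide_id
      ann_path <- mask_path <- hm_path <- NA_character_
      if (nrow(sl$annotations) > 0) {
        ann_path <- file.path("annotations", paste0(id, ".xml"))
        write_asap_xml(sl$annotations$polygon,
                       file.path(output_dir, ann_path),
                       names = sprintf("lesion_%d", sl$annotations$lesion_id))
      }
      if (write_masks) {
        mask <- label_mask(sl$annotations, sl$raster$tissue,
                           spec$raster_spacing_um)
        mask_path <- file.path("masks", paste0(id, "_mask.tif"))
        write_mask_tiff(mask, file.path(output_dir, mask_path))
      }
      hm <- generate_heatmap(sl$annotations, hspec,
                             dim(sl$raster$tissue), spec$raster_spacing_um,
                             seed_index = derive_seed(spec$seed, i, 13L))
      if (write_heatmaps) {
        hm_path <- file.path("heatmaps", paste0(id, "_heatmap.tif"))
        write_heatmap_tiff(hm, file.path(output_dir, hm_path))
      }
      pl <- attr(hm, "planted")
      if (nrow(pl) > 0) {
        pl$slide_id <- id
        planted_all[[length(planted_all) + 1L]] <- pl
      }
      rec <- sl$record
      rec$annotation_path <- ann_path
      rec$mask_path <- mask_path
      rec$heatmap_path <- hm_path
      records[[length(records) + 1L]] <- rec
    }
  }
  manifest <- dplyr::bind_rows(records)
  if (nrow(manifest) == 0) {
    manifest <- tibble::tibble(slide_id = character(), dataset = character(),
                               gt_label = character(), split = character())
  }
  utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  planted <- dplyr::bind_rows(planted_all)
  utils::write.csv(planted, file.path(output_dir, "planted.csv"),
                   row.names = FALSE)
  manifest
}

#' Sample a labeled patch set from slide rasters
#'
#' Draws `n_patches` square patches whose labels come from the mask code at
#' the patch center: tumor (code 2) with probability `tumor_fraction`,
#' healthy (code 1) otherwise. Patch pixels are read from the slide's
#' working raster (nearest-neighbor resampled from raster spacing to
#' `pixel_spacing_um`) and rendered as 3-channel arrays with a
#' class-dependent chromatic shift plus fine-scale noise, standing in for
#' H&E appearance.
#'
#' @param slides List of slides as returned by [generate_slide()]; each needs
#'   `raster` and `annotations`.
#' @param n_patches Number of patches.
#' @param tumor_fraction Probability a patch is tumor-centered.
#' @param patch_px Patch side in pixels at `pixel_spacing_um`.
#' @param pixel_spacing_um Patch pixel spacing, micrometers (default 0.5).
#' @param seed Integer seed.
#' @return List with `patches` (array `n x patch_px x patch_px x 3` in
#'   `[0, 1]`) and `labels` (tibble: `patch_id`, `slide`, `label`
#'   `"tumor"`/`"healthy"`, center coordinates in micrometers).
#' @export
generate_patch_set <- function(slides, n_patches, tumor_fraction = 0.2,
                               patch_px = 279, pixel_spacing_um = 0.5,
                               seed = 1L) {
  stopifnot(tumor_fraction >= 0, tumor_fraction <= 1, n_patches >= 0)
  masks <- lapply(slides, function(sl) {
    label_mask(sl$annotations, sl$raster$tissue, sl$raster$spacing_um)
  })
  tumor_px <- lapply(masks, function(m) which(m == 2L))
  healthy_px <- lapply(masks, function(m) which(m == 1L))
  have_tumor <- which(vapply(tumor_px, length, integer(1)) > 0)
  have_healthy <- which(vapply(healthy_px, length, integer(1)) > 0)
  if (tumor_fraction > 0 && length(have_tumor) == 0) {
    stop("no tumor pixels available but tumor_fraction > 0")
  }
  if (tumor_fraction < 1 && length(have_healthy) == 0) {
    stop("no healthy pixels available")
  }
  with_seed(seed, {
    is_tumor <- stats::runif(n_patches) < tumor_fraction
    patches <- array(0, c(n_patches, patch_px, patch_px, 3))
    rows <- vector("list", n_patches)
    for (p in seq_len(n_patches)) {
      pool <- if (is_tumor[p]) have_tumor else have_healthy
      s <- pool[sample.int(length(pool), 1L)]
      px <- if (is_tumor[p]) tumor_px[[s]] else healthy_px[[s]]
      ctr <- px[sample.int(length(px), 1L)]
      m <- masks[[s]]
      h <- nrow(m)
      ri <- ((ctr - 1L) %% h) + 1L
      ci <- ((ctr - 1L) %/% h) + 1L
      patches[p, , , ] <- render_patch(slides[[s]]$raster, masks[[s]],
                                       ri, ci, patch_px, pixel_spacing_um)
      rows[[p]] <- tibble::tibble(
        patch_id = p, slide = s,
        label = if (is_tumor[p]) "tumor" else "healthy",
        cx_um = (ci - 0.5) * slides[[s]]$raster$spacing_um,
        cy_um = (ri - 0.5) * slides[[s]]$raster$spacing_um
      )
    }
    list(patches = patches, labels = dplyr::bind_rows(rows))
  })
}

# nearest-neighbor read of a patch around raster pixel (ri, ci), plus a
# class-dependent chromatic rendering and iid fine-scale noise
render_patch <- function(raster, mask, ri, ci, patch_px, pixel_spacing_um) {
  ratio <- raster$spacing_um / pixel_spacing_um
  off <- seq_len(patch_px) - (patch_px + 1) / 2
  rr <- pmin(pmax(ri + round(off / ratio), 1L), nrow(mask))
  cc <- pmin(pmax(ci + round(off / ratio), 1L), ncol(mask))
  inten <- raster$intensity[rr, cc]
  code <- mask[rr, cc]
  out <- array(0, c(patch_px, patch_px, 3))
  # healthy tissue rendered pink-ish, tumor regions darker and bluer
  tumor <- code == 2L
  r_ch <- inten * 0.95; g_ch <- inten * 0.75; b_ch <- inten * 0.85
  r_ch[tumor] <- inten[tumor] * 0.55
  g_ch[tumor] <- inten[tumor] * 0.45
  b_ch[tumor] <- inten[tumor] * 0.75
  out[, , 1] <- r_ch; out[, , 2] <- g_ch; out[, , 3] <- b_ch
  noise <- array(stats::rnorm(length(out), 0, 0.02), dim(out))
  pmin(pmax(out + noise, 0), 1)
}
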