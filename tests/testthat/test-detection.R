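# helper: heatmap with a filled disc of the given score and diameter (mm)
disc_heatmap <- function(d_mm, score = 0.8, spacing_um = 10, extent_px = 80,
                         background = 0) {
  ell <- tibble::tibble(cx_um = extent_px * spacing_um / 2,
                        cy_um = extent_px * spacing_um / 2,
                        major_um = d_mm * 1000, minor_um = d_mm * 1000,
                        angle = 0)
  s <- matrix(background, extent_px, extent_px)
  s[rasterize_ellipses(ell, c(extent_px, extent_px), spacing_um)] <- score
  new_heatmap(s, spacing_um)
}

test_that("an all-zero heatmap yields no detections", {
  hm <- new_heatmap(matrix(0, 30, 30), 10)
  expect_equal(nrow(extract_detections(hm)), 0)
})

test_that("a single planted blob yields one region with its argmax point", {
  s <- matrix(0, 40, 40)
  s[10:20, 12:22] <- 0.7
  s[15, 17] <- 0.93
  hm <- new_heatmap(s, 10)
  det <- extract_detections(hm)
  expect_equal(nrow(det), 1)
  expect_equal(det$score, 0.93)
  expect_equal(det$x_um, (17 - 0.5) * 10)
  expect_equal(det$y_um, (15 - 0.5) * 10)
})

test_that("diagonally touching blobs merge under the 8-connectivity rule", {
  s <- matrix(0, 20, 20)
  s[5:7, 5:7] <- 0.9
  s[8:10, 8:10] <- 0.9   # touches (7,7) diagonally
  hm <- new_heatmap(s, 10)
  det <- extract_detections(hm)
  expect_equal(nrow(det), 1)
  lab <- canonical_labels(flood_fill_label(s >= 0.5, 8))
  expect_equal(max(lab), 1L)
})

test_that("pixels at exactly the threshold are retained", {
  s <- matrix(0, 10, 10)
  s[4, 4] <- 0.5
  det <- extract_detections(new_heatmap(s, 10), threshold = 0.5)
  expect_equal(nrow(det), 1)
  s[4, 4] <- 0.4999
  expect_equal(nrow(extract_detections(new_heatmap(s, 10), 0.5)), 0)
})

test_that("ITC-size filtering drops strictly-below-0.2 mm regions only", {
  det <- tibble::tibble(region_id = 1:3, score = c(0.9, 0.8, 0.7),
                        x_um = 0, y_um = 0,
                        diameter_mm = c(0.1, 0.2, 0.5),
                        n_px = 1L, centroid_x_um = 0, centroid_y_um = 0,
                        pixels = list(1L, 2L, 3L))
  kept <- filter_itc_size(det)
  expect_equal(kept$diameter_mm, c(0.2, 0.5))
  # idempotent and monotone in the cutoff
  expect_identical(filter_itc_size(kept), kept)
  expect_true(nrow(filter_itc_size(det, 0.3)) <= nrow(kept))
  expect_equal(nrow(filter_itc_size(det[0, ])), 0)
  expect_equal(nrow(filter_itc_size(dplyr::mutate(det, diameter_mm = 0.01))),
               0)
})

test_that("slide labels follow the TNM boundaries on retained detections", {
  mk <- function(d) tibble::tibble(diameter_mm = d, score = 0.9)
  expect_equal(assign_slide_label(mk(2.5)), "macro")
  expect_equal(assign_slide_label(mk(2.01)), "macro")
  expect_equal(assign_slide_label(mk(2.0)), "micro")
  expect_equal(assign_slide_label(mk(1.0)), "micro")
  expect_equal(assign_slide_label(mk(0.21)), "micro")
  # a region of exactly 0.2 mm survives the filter but labels negative
  expect_equal(assign_slide_label(mk(0.2)), "negative")
  expect_equal(assign_slide_label(mk(c(0.19, 1.5))), "micro")
  expect_equal(assign_slide_label(mk(numeric())), "negative")
})

test_that("slide score is the max retained score, 0 with nothing retained", {
  det <- tibble::tibble(score = c(0.7, 0.95), diameter_mm = c(0.5, 0.3))
  expect_equal(slide_score(det), 0.95)
  expect_equal(slide_score(det[0, ]), 0)
  expect_equal(slide_score(tibble::tibble(score = 0.5, diameter_mm = 1)), 0.5)
})

test_that("detection sizing matches the planted diameter through the filter", {
  big <- disc_heatmap(0.5)    # 0.5 mm disc
  small <- disc_heatmap(0.1)  # ITC-sized
  expect_equal(nrow(filter_itc_size(extract_detections(big))), 1)
  expect_equal(nrow(filter_itc_size(extract_detections(small))), 0)
})

test_that("detections export to ASAP XML and round-trip", {
  hm <- disc_heatmap(0.4, score = 0.9)
  det <- extract_detections(hm)
  path <- withr::local_tempfile(fileext = ".xml")
  export_asap_xml(det, hm, path, slide_id = "s1")
  rd <- read_asap_xml(path)
  expect_equal(nrow(rd), 1)
  expect_equal(rd$name, "s1_detection_1")
  # the hull contains the detection point
  expect_false(is.na(points_in_polygons(det$x_um, det$y_um, rd$polygon)))
  # write-then-read of an empty detection set is valid
  export_asap_xml(det[0, ], hm, path)
  expect_equal(nrow(read_asap_xml(path)), 0)
  # polygon vertices survive a write/read cycle
  poly <- ellipse_polygon(300, 350, 200, 120, 0.3, n = 16)
  write_asap_xml(list(poly), path)
  back <- read_asap_xml(path)$polygon[[1]]
  expect_equal(back, unname(poly[-nrow(poly), ]), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("missing spacing metadata is an error", {
  expect_error(new_heatmap(matrix(0.1, 4, 4), -1))
  expect_error(read_heatmap_tiff(withr::local_tempfile(fileext = ".tif")))
})
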