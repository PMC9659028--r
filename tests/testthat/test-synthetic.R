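spec_micro <- cohort_spec("S", n_negative = 2, n_positive = 3,
                          slide_extent_mm = 5, raster_spacing_um = 16,
                          micro_fraction = 1, seed = 5)

test_that("negative-only cohorts plant nothing and label negative", {
  spec <- cohort_spec("N", n_negative = 2, n_positive = 0,
                      slide_extent_mm = 5, raster_spacing_um = 16, seed = 2)
  sl <- generate_slide(spec, 1)
  expect_equal(sl$record$gt_label, "negative")
  expect_equal(nrow(sl$annotations), 0)
})

test_that("forced micro cohorts stay in the micro band and are so labeled", {
  for (i in 3:5) {
    sl <- generate_slide(spec_micro, i)
    expect_gt(nrow(sl$annotations), 0)
    expect_true(all(sl$annotations$diameter_mm > 0.2 &
                      sl$annotations$diameter_mm <= 2))
    expect_equal(sl$record$gt_label, "micro")
  }
})

test_that("slide labels follow the TNM rule on the largest planted lesion", {
  spec <- cohort_spec("M", n_negative = 0, n_positive = 8,
                      slide_extent_mm = 9, raster_spacing_um = 16,
                      micro_fraction = 0.5, macro_range_mm = c(2.2, 3),
                      seed = 8)
  for (i in 1:8) {
    sl <- generate_slide(spec, i)
    expect_equal(sl$record$gt_label,
                 tnm_label(max(sl$annotations$diameter_mm)))
  }
})

test_that("generators are pure functions of their seeds", {
  expect_identical(generate_slide(spec_micro, 4), generate_slide(spec_micro, 4))
  hs <- heatmap_spec(fp_blob_rate = 3, seed = 4)
  sl <- generate_slide(spec_micro, 4)
  h1 <- generate_heatmap(sl$annotations, hs, c(100, 100), 16, seed_index = 1)
  h2 <- generate_heatmap(sl$annotations, hs, c(100, 100), 16, seed_index = 1)
  expect_identical(h1, h2)
  h3 <- generate_heatmap(sl$annotations, hs, c(100, 100), 16, seed_index = 2)
  expect_false(identical(h1$scores, h3$scores))
})

test_that("slides that cannot hold the requested lesions are rejected", {
  expect_error(
    cohort_spec("X", n_positive = 1, slide_extent_mm = 3,
                macro_range_mm = c(2.5, 8), micro_fraction = 0),
    "cannot hold")
})

test_that("degenerate heatmap specs recover the planted signal exactly", {
  sl <- generate_slide(spec_micro, 3)
  hs <- heatmap_spec(in_lesion_score = c(1, 0), fp_blob_rate = 0)
  hm <- generate_heatmap(sl$annotations, hs, dim(sl$raster$tissue), 16,
                         seed_index = 3)
  lesion_px <- rasterize_polygons(sl$annotations$polygon,
                                  dim(sl$raster$tissue), 16)
  expect_true(all(hm$scores[lesion_px] == 1))
  expect_lt(max(hm$scores[!lesion_px]), 0.5)
  # no lesions, no blobs: nothing near the detection threshold
  hm0 <- generate_heatmap(NULL, hs, c(80, 80), 16, seed_index = 1)
  expect_lt(max(hm0$scores), 0.5)
})

test_that("confounder blobs appear at the configured Poisson rate", {
  hs <- heatmap_spec(fp_blob_rate = 4, seed = 10)
  n <- vapply(1:40, function(i) {
    hm <- generate_heatmap(NULL, hs, c(500, 500), 16, seed_index = i)
    det <- filter_itc_size(extract_detections(hm))
    nrow(det)
  }, numeric(1))
  # mean within 3 standard errors of the rate, and detections match planting
  expect_lt(abs(mean(n) - 4), 3 * sqrt(4 / 40))
})

test_that("cohort assets are written, counted, and byte-stable", {
  dir1 <- withr::local_tempdir()
  hs <- heatmap_spec(fp_blob_rate = 0.5, seed = 2)
  m <- generate_cohort(spec_micro, hs, file.path(dir1, "a"))
  expect_equal(nrow(m), 5)
  expect_true(file.exists(file.path(dir1, "a", "manifest.csv")))
  expect_equal(sum(!is.na(m$annotation_path)), 3)
  expect_error(generate_cohort(spec_micro, hs, file.path(dir1, "a")),
               "overwrite")
  generate_cohort(spec_micro, hs, file.path(dir1, "b"))
  expect_identical(readLines(file.path(dir1, "a", "manifest.csv")),
                   readLines(file.path(dir1, "b", "manifest.csv")))
  # empty spec list
  m0 <- generate_cohort(list(), hs, file.path(dir1, "c"))
  expect_equal(nrow(m0), 0)
})

test_that("patch sets honor the tumor fraction and center-pixel labels", {
  slides <- lapply(1:4, function(i) generate_slide(spec_micro, i + 1))
  ps <- generate_patch_set(slides, n_patches = 800, tumor_fraction = 0.2,
                           patch_px = 9, seed = 3)
  n_tumor <- sum(ps$labels$label == "tumor")
  expect_lt(abs(n_tumor - 160), 3 * sqrt(800 * 0.2 * 0.8))
  expect_equal(dim(ps$patches), c(800, 9, 9, 3))
  expect_true(all(ps$patches >= 0 & ps$patches <= 1))
  # all-healthy edge case
  ps0 <- generate_patch_set(slides, 50, tumor_fraction = 0, patch_px = 9,
                            seed = 4)
  expect_true(all(ps0$labels$label == "healthy"))
  # no tumor pixels but tumor requested
  neg <- lapply(1:2, function(i) generate_slide(spec_micro, i))
  expect_error(generate_patch_set(neg, 10, tumor_fraction = 0.5,
                                  patch_px = 9),
               "no tumor pixels")
})

test_that("label masks code background/healthy/tumor consistently", {
  sl <- generate_slide(spec_micro, 4)
  mask <- label_mask(sl$annotations, sl$raster$tissue, 16)
  expect_setequal(unique(as.vector(mask)), c(0L, 1L, 2L))
  tumor <- rasterize_polygons(sl$annotations$polygon, dim(mask), 16)
  expect_identical(mask == 2L, tumor)
  expect_true(all(mask[!sl$raster$tissue & !tumor] == 0L))
})
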