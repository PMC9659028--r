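#' Render a whole synthetic slide as an RGB raster
#'
#' Applies the same chromatic rendering used for training patches to the
#' full working raster, so a network trained on synthetic patches can be
#' applied fully convolutionally to the slide.
#'
#' @param slide A slide from [generate_slide()].
#' @param mask Optional precomputed label mask.
#' @param noise_sd Fine-scale noise level.
#' @param seed Integer seed for the noise.
#' @return `(H, W, 3)` array in `[0, 1]`.
#' @export
render_slide_rgb <- function(slide, mask = NULL, noise_sd = 0.02, seed = 1L) {
  if (is.null(mask)) {
    mask <- label_mask(slide$annotations, slide$raster$tissue,
                       slide$raster$spacing_um)
  }
  inten <- slide$raster$intensity
  tumor <- mask == 2L
  out <- array(0, c(dim(inten), 3))
  r_ch <- inten * 0.95; g_ch <- inten * 0.75; b_ch <- inten * 0.85
  r_ch[tumor] <- inten[tumor] * 0.55
  g_ch[tumor] <- inten[tumor] * 0.45
  b_ch[tumor] <- inten[tumor] * 0.75
  out[, , 1] <- r_ch; out[, , 2] <- g_ch; out[, , 3] <- b_ch
  with_seed(seed, {
    out <- out + array(stats::rnorm(length(out), 0, noise_sd), dim(out))
  })
  pmin(pmax(out, 0), 1)
}

#' Default pipeline run configuration
#'
#' A toy-scale end-to-end configuration: simulate a cohort, split it,
#' post-process heatmaps (synthetic by default) into detections, mine hard
#' negatives, and evaluate with bootstrap intervals. All blocks can be
#' overridden from a YAML file with the same structure.
#'
#' @param output_dir Run directory.
#' @param seed Master seed; per-stage seeds derive from it.
#' @return Nested configuration list.
#' @export
default_run_config <- function(output_dir = "slidemets_run", seed = 1L) {
  list(
    output_dir = output_dir,
    seed = as.integer(seed),
    cohorts = list(
      list(dataset_name = "SynthSentinel", n_negative = 12, n_positive = 8,
           slide_extent_mm = 8, raster_spacing_um = 16,
           macro_range_mm = c(2.5, 3.5), micro_fraction = 0.6)
    ),
    heatmap = list(source = "synthetic", in_lesion_score = c(0.95, 0.02),
                   background_score = c(0.05, 0.02), fp_blob_rate = 1.3),
    split = list(train_frac = 0.5, val_frac = 0.2),
    evaluation = list(threshold = 0.5, min_diameter_mm = 0.2,
                      n_bootstrap = 500, n_permutations = 500),
    train = list(enabled = FALSE, patches_per_epoch = 256, patch_px = 9,
                 max_epochs = 3, batch_size = 32,
                 network = list(n_dense_blocks = 1, convs_3x3_per_block = 3,
                                channels_1x1 = 8, channels_3x3 = 8))
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; missing blocks fall back to
#'   [default_run_config()] values.
#' @param seed Optional seed override.
#' @return Configuration list.
#' @export
read_run_config <- function(path, seed = NULL) {
  loaded <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(loaded)) {
    # cohorts is an unnamed list of blocks: replace, never merge
    if (nm != "cohorts" && is.list(cfg[[nm]]) && is.list(loaded[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], loaded[[nm]])
    } else {
      cfg[[nm]] <- loaded[[nm]]
    }
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

config_hash <- function(config) rlang::hash(config)

stage_fresh <- function(config, stage) {
  f <- file.path(config$output_dir, paste0(".", stage, ".hash"))
  file.exists(f) && identical(readLines(f, warn = FALSE),
                              config_hash(config))
}

stage_done <- function(config, stage) {
  writeLines(config_hash(config),
             file.path(config$output_dir, paste0(".", stage, ".hash")))
}

cohort_spec_from_config <- function(block, seed) {
  args <- block
  args$seed <- derive_seed(seed, 1L, nchar(block$dataset_name))
  do.call(cohort_spec, args)
}

heatmap_spec_from_config <- function(block, seed) {
  args <- block[setdiff(names(block), "source")]
  args$seed <- derive_seed(seed, 2L)
  do.call(heatmap_spec, args)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from (and writes its outputs under)
#' `config$output_dir`, is deterministic given the config, and records the
#' config hash so downstream stages can detect stale inputs.
#' `pipeline_simulate()` writes the synthetic cohort assets;
#' `pipeline_split()` applies a stratified split to the manifest;
#' `pipeline_evaluate()` post-processes heatmaps into detections, TNM slide
#' labels and an evaluation report (`evaluation.json`, `predictions.csv`);
#' `pipeline_mine()` adds hard-negative regions to the label masks;
#' `pipeline_compare()` permutation-tests two datasets against each other.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @param datasets For [pipeline_compare()]: the two dataset names.
#' @param force Re-run even when the stage is up to date.
#' @return Each stage returns its main artifact invisibly (manifest,
#'   evaluation list, ...).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config, force = FALSE) {
  if (!force && stage_fresh(config, "simulate")) {
    return(invisible(read_manifest(file.path(config$output_dir,
                                             "manifest.csv"))))
  }
  specs <- lapply(config$cohorts, cohort_spec_from_config,
                  seed = config$seed)
  hspec <- heatmap_spec_from_config(config$heatmap, config$seed)
  manifest <- generate_cohort(specs, hspec, config$output_dir,
                              overwrite = TRUE)
  stage_done(config, "simulate")
  invisible(manifest)
}

#' @rdname pipeline
#' @export
pipeline_split <- function(config, force = FALSE) {
  path <- file.path(config$output_dir, "manifest.csv")
  if (!file.exists(path)) stop("missing upstream artifact for stage split: ",
                               path, " (run simulate first)")
  manifest <- read_manifest(path)
  manifest <- exclude_itc(manifest)
  manifest$split <- "unassigned"  # the config owns the split; reruns idempotent
  counts <- manifest |>
    dplyr::mutate(class = ifelse(is_positive_label(.data$gt_label),
                                 "positive", "negative")) |>
    dplyr::count(.data$dataset, .data$class)
  targets <- counts |>
    dplyr::mutate(
      n_train = floor(.data$n * config$split$train_frac),
      n_val = floor(.data$n * config$split$val_frac),
      n_test = .data$n - .data$n_train - .data$n_val
    )
  manifest <- stratified_split(manifest, targets,
                               seed = derive_seed(config$seed, 3L))
  utils::write.csv(manifest, path, row.names = FALSE)
  stage_done(config, "split")
  invisible(manifest)
}

# load heatmap + annotations for one manifest row
slide_assets <- function(config, rec) {
  hm <- read_heatmap_tiff(file.path(config$output_dir, rec$heatmap_path))
  ann <- if (!is.na(rec$annotation_path)) {
    read_asap_xml(file.path(config$output_dir, rec$annotation_path))
  } else {
    tibble::tibble(name = character(), polygon = list())
  }
  list(heatmap = hm, annotations = ann)
}

#' @rdname pipeline
#' @export
pipeline_evaluate <- function(config, force = FALSE) {
  manifest <- read_manifest(file.path(config$output_dir, "manifest.csv"))
  if (!"heatmap_path" %in% names(manifest)) {
    stop("missing upstream artifact for stage evaluate: heatmaps")
  }
  ev <- config$evaluation
  dets <- list(); lesions <- list(); preds <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    assets <- slide_assets(config, rec)
    pr <- predict_slide_label(assets$heatmap, rec$slide_id,
                              threshold = ev$threshold,
                              min_diameter_mm = ev$min_diameter_mm)
    d <- pr$detections
    if (nrow(d)) {
      d$slide_id <- rec$slide_id
      dets[[length(dets) + 1L]] <-
        d[, c("slide_id", "x_um", "y_um", "score")]
    }
    if (nrow(assets$annotations)) {
      lesions[[length(lesions) + 1L]] <- tibble::tibble(
        slide_id = rec$slide_id,
        lesion_id = seq_len(nrow(assets$annotations)),
        polygon = assets$annotations$polygon
      )
    }
    preds[[i]] <- tibble::tibble(
      slide_id = rec$slide_id, gt_label = rec$gt_label,
      predicted_label = pr$predicted_label, slide_score = pr$slide_score,
      n_detections = nrow(d)
    )
  }
  preds <- dplyr::bind_rows(preds)
  summ <- summarize_slides(
    tibble::tibble(slide_id = manifest$slide_id,
                   positive = is_positive_label(manifest$gt_label),
                   slide_score = preds$slide_score),
    dplyr::bind_rows(dets) %||%
      tibble::tibble(slide_id = character(), x_um = double(),
                     y_um = double(), score = double()),
    dplyr::bind_rows(lesions))
  res <- evaluate_slides(summ, n_bootstrap = ev$n_bootstrap,
                         seed = derive_seed(config$seed, 4L))
  utils::write.csv(preds, file.path(config$output_dir, "predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(auc = res$auc, froc = res$froc, auc_ci = res$auc_ci,
         froc_ci = res$froc_ci, n_slides = res$n_slides,
         n_bootstrap = res$n_bootstrap, config_hash = config_hash(config)),
    file.path(config$output_dir, "evaluation.json"),
    auto_unbox = TRUE, digits = NA)
  stage_done(config, "evaluate")
  invisible(list(result = res, predictions = preds, summary = summ))
}

#' @rdname pipeline
#' @export
pipeline_mine <- function(config, force = FALSE) {
  manifest <- read_manifest(file.path(config$output_dir, "manifest.csv"))
  if (!all(c("heatmap_path", "mask_path") %in% names(manifest))) {
    stop("missing upstream artifact for stage mine: heatmaps/masks")
  }
  ev <- config$evaluation
  n_regions <- 0L
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    if (is.na(rec$mask_path)) next
    assets <- slide_assets(config, rec)
    regions <- mine_hard_negatives(assets$heatmap, assets$annotations,
                                   threshold = ev$threshold)
    if (nrow(regions)) {
      mpath <- file.path(config$output_dir, rec$mask_path)
      mask <- update_label_mask(read_mask_tiff(mpath), regions)
      write_mask_tiff(mask, mpath)
      n_regions <- n_regions + nrow(regions)
    }
  }
  stage_done(config, "mine")
  invisible(n_regions)
}

#' @rdname pipeline
#' @export
pipeline_compare <- function(config, datasets, force = FALSE) {
  stopifnot(length(datasets) == 2)
  evald <- pipeline_evaluate(config, force = TRUE)
  summ <- evald$summary
  manifest <- read_manifest(file.path(config$output_dir, "manifest.csv"))
  ds_of <- manifest$dataset[match(summ$slide_id, manifest$slide_id)]
  a <- summ[ds_of == datasets[1], ]
  b <- summ[ds_of == datasets[2], ]
  out <- list()
  for (st in c("auc", "froc")) {
    pt <- permutation_test(a, b, statistic = st,
                           n = config$evaluation$n_permutations,
                           seed = derive_seed(config$seed, 5L))
    out[[paste0("p_", st)]] <- pt$p_value
    out[[paste0("delta_", st)]] <- pt$observed
  }
  jsonlite::write_json(out, file.path(config$output_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_done(config, "compare")
  invisible(out)
}

#' Run pipeline stages in order
#'
#' @param config Configuration list or path to a YAML file.
#' @param stages Character vector of stages to run, in order.
#' @param seed Optional seed override.
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "split", "evaluate"),
                         seed = NULL) {
  if (is.character(config)) config <- read_run_config(config, seed)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  for (st in stages) {
    fn <- switch(st,
                 simulate = pipeline_simulate,
                 split = pipeline_split,
                 evaluate = pipeline_evaluate,
                 mine = pipeline_mine,
                 stop("unknown stage: ", st))
    res[[st]] <- fn(config)
  }
  invisible(res)
}
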