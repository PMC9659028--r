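#' Composition of the lymph-node generalization study
#'
#' Returns the published per-dataset composition of the study cohorts as a
#' tidy table: slide counts per dataset and class, the isolated-tumor-cell
#' (ITC) positives that are excluded before analysis, the per-split target
#' counts, and the extra-nodal "enrichment" negatives added to the axillary
#' training data. Counts cover four sources: two local Swedish datasets
#' (sentinel-node and axillary-dissection procedures) and the two CAMELYON
#' multicenter sentinel-node datasets.
#'
#' @return A tibble with one row per (dataset, class, enrichment) cell and
#'   columns `dataset`, `procedure`, `class` (`"negative"`/`"positive"`),
#'   `n`, `n_itc_only` (positives that carry only ITC-sized deposits and are
#'   excluded), `n_train`, `n_val`, `n_test` (split targets for the non-ITC
#'   slides), `fixed_split` (whether the source ships pre-generated splits),
#'   `enrichment` (extra-nodal negatives added to train/val only), and the
#'   test-set subtype breakdown `n_test_ilc`.
#' @export
study_composition <- function() {
  tibble::tribble(
    ~dataset,        ~procedure, ~class,      ~n,  ~n_itc_only, ~n_train, ~n_val, ~n_test, ~fixed_split, ~enrichment, ~n_test_ilc,
    "CAMELYON16",     "sentinel", "negative", 239L, 0L,          127L,     32L,    80L,     TRUE,         FALSE,       0L,
    "CAMELYON16",     "sentinel", "positive", 160L, 0L,           89L,     22L,    49L,     TRUE,         FALSE,       6L,
    "CAMELYON17",     "sentinel", "negative", 310L, 0L,           40L,     10L,   260L,     TRUE,         FALSE,       0L,
    "CAMELYON17",     "sentinel", "positive",  50L, 16L,          15L,      9L,    10L,     TRUE,         FALSE,       0L,
    "LocalSentinel",  "sentinel", "negative", 107L, 0L,           58L,     15L,    34L,     FALSE,        FALSE,       0L,
    "LocalSentinel",  "sentinel", "positive",  54L, 0L,           30L,      7L,    17L,     FALSE,        FALSE,       6L,
    "LocalAxillary",  "axillary", "negative",  24L, 0L,           11L,      3L,    10L,     FALSE,        FALSE,       0L,
    "LocalAxillary",  "axillary", "positive",  24L, 0L,           13L,      4L,     7L,     FALSE,        FALSE,       2L,
    "LocalAxillary",  "axillary", "negative",   9L, 0L,            6L,      3L,     0L,     TRUE,         TRUE,        0L
  )
}

#' Build a study manifest from a composition table
#'
#' Expands a per-dataset composition description into one record per slide.
#' Positive slides without a recorded micro/macro breakdown get the coarse
#' label `"positive"`; ITC-only positives get `"itc_only"` and are meant to
#' be removed by [exclude_itc()] before analysis. Slides from sources with
#' pre-generated splits come back with their split already assigned; all
#' others are `"unassigned"` until [stratified_split()].
#'
#' @param composition A tibble in the shape of [study_composition()]. Columns
#'   `n_itc_only`, `fixed_split`, `enrichment`, `n_test_ilc` are optional and
#'   default to 0/FALSE.
#' @param spacing_um Pixel spacing recorded per slide (default 0.5).
#' @return A manifest tibble with columns `slide_id`, `dataset`, `procedure`,
#'   `subtype`, `gt_label`, `split`, `annotation_status`, `enrichment`,
#'   `spacing_um`.
#' @export
build_manifest <- function(composition, spacing_um = 0.5) {
  comp <- tibble::as_tibble(composition)
  stopifnot(all(c("dataset", "class", "n") %in% names(comp)))
  if (any(comp$n < 0)) stop("composition counts must be non-negative")
  for (col in c("n_itc_only", "n_train", "n_val", "n_test", "n_test_ilc")) {
    if (!col %in% names(comp)) comp[[col]] <- 0L
  }
  if (!"fixed_split" %in% names(comp)) comp$fixed_split <- FALSE
  if (!"enrichment" %in% names(comp)) comp$enrichment <- FALSE
  if (!"procedure" %in% names(comp)) comp$procedure <- "sentinel"
  if (nrow(comp) == 0L) {
    return(tibble::tibble(
      slide_id = character(), dataset = character(), procedure = character(),
      subtype = character(), gt_label = character(), split = character(),
      annotation_status = character(), enrichment = logical(),
      spacing_um = double()
    ))
  }
  dup <- duplicated(comp[, c("dataset", "class", "enrichment")])
  if (any(dup)) stop("duplicate (dataset, class) rows in composition")
  if (any(comp$n_itc_only > comp$n)) stop("n_itc_only exceeds n")
  bad <- comp$n_train + comp$n_val + comp$n_test != comp$n - comp$n_itc_only
  if (any(bad & (comp$n_train + comp$n_val + comp$n_test > 0))) {
    stop("split targets must sum to the post-ITC class total")
  }

  rows <- purrr::pmap(comp, function(dataset, procedure, class, n, n_itc_only,
                                     n_train, n_val, n_test, fixed_split,
                                     enrichment, n_test_ilc, ...) {
    if (n == 0L) return(NULL)
    gt <- if (class == "negative") rep("negative", n) else {
      c(rep("positive", n - n_itc_only), rep("itc_only", n_itc_only))
    }
    split <- rep("unassigned", n)
    subtype <- rep("unknown", n)
    if (fixed_split) {
      # pre-generated source splits: assign deterministically in id order,
      # ITC-only records last and unassigned (they are excluded anyway)
      split[seq_len(n - n_itc_only)] <-
        rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
    }
    if (n_test_ilc > 0) {
      # subtype breakdown published for test positives only
      test_idx <- if (fixed_split) which(split == "test") else seq_len(n)
      subtype[test_idx[seq_len(n_test_ilc)]] <- "ILC"
    }
    tag <- if (enrichment) "enr" else substr(class, 1, 3)
    tibble::tibble(
      slide_id = sprintf("%s_%s_%03d", dataset, tag, seq_len(n)),
      dataset = dataset,
      procedure = procedure,
      subtype = subtype,
      gt_label = gt,
      split = split,
      annotation_status = ifelse(gt == "negative", "none", "full"),
      enrichment = enrichment,
      spacing_um = spacing_um
    )
  })
  manifest <- dplyr::bind_rows(rows)
  if (anyDuplicated(manifest$slide_id)) stop("slide ids are not unique")
  manifest
}

#' Remove ITC-only slides from a manifest
#'
#' Slides whose only deposits are isolated tumor cells (<= 0.2 mm) are
#' node-negative under TNM but were never part of the detection task; they
#' are excluded from training and evaluation. Record order is preserved and
#' the operation is idempotent.
#'
#' @param manifest A manifest tibble.
#' @return The manifest without `gt_label == "itc_only"` rows.
#' @export
exclude_itc <- function(manifest) {
  dplyr::filter(manifest, .data$gt_label != "itc_only")
}

#' Stratified train/validation/test split
#'
#' Assigns each unassigned slide to a split by exact-count stratified
#' sampling within (dataset, class) cells, so every cell holds exactly its
#' target count. Records that already carry a fixed split (pre-generated
#' source splits) are left untouched.
#'
#' @param manifest Manifest tibble.
#' @param targets Tibble with columns `dataset`, `class`, `n_train`, `n_val`,
#'   `n_test`; defaults to the published split targets from
#'   [study_composition()].
#' @param seed Integer seed for the random assignment.
#' @return The manifest with `split` filled in.
#' @export
stratified_split <- function(manifest, targets = NULL, seed = 1L) {
  if (is.null(targets)) {
    targets <- study_composition() |>
      dplyr::filter(!.data$fixed_split) |>
      dplyr::group_by(.data$dataset, .data$class) |>
      dplyr::summarise(dplyr::across(c("n_train", "n_val", "n_test"), sum),
                       .groups = "drop")
  }
  out <- manifest
  with_seed(seed, {
    for (k in seq_len(nrow(targets))) {
      tg <- targets[k, ]
      cls <- ifelse(is_positive_label(out$gt_label), "positive", "negative")
      idx <- which(out$dataset == tg$dataset & cls == tg$class &
                     out$split == "unassigned")
      need <- tg$n_train + tg$n_val + tg$n_test
      if (length(idx) < need) {
        stop(sprintf("infeasible split targets for %s/%s: need %d, have %d",
                     tg$dataset, tg$class, need, length(idx)))
      }
      take <- sample_exact(idx, need)
      out$split[take] <- rep(c("train", "val", "test"),
                             times = c(tg$n_train, tg$n_val, tg$n_test))
    }
  })
  out
}

#' Summarize a manifest as split-by-class counts
#'
#' @param manifest Manifest tibble.
#' @return Tibble with one row per dataset plus a totals row, and columns
#'   `n`, `n_neg`, `n_pos` overall and per split.
#' @export
manifest_counts <- function(manifest) {
  one <- function(df) {
    pos <- is_positive_label(df$gt_label)
    tibble::tibble(
      n = nrow(df), n_neg = sum(!pos), n_pos = sum(pos),
      train = sum(df$split == "train"),
      train_neg = sum(df$split == "train" & !pos),
      train_pos = sum(df$split == "train" & pos),
      val = sum(df$split == "val"),
      val_neg = sum(df$split == "val" & !pos),
      val_pos = sum(df$split == "val" & pos),
      test = sum(df$split == "test"),
      test_neg = sum(df$split == "test" & !pos),
      test_pos = sum(df$split == "test" & pos)
    )
  }
  per <- manifest |>
    dplyr::group_by(.data$dataset) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
  dplyr::bind_rows(per, dplyr::bind_cols(tibble::tibble(dataset = "Total"),
                                         one(manifest)))
}
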