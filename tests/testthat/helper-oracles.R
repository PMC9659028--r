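# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations: flood fill instead of sparse labeling,
# all-pairs counting instead of ranks, direct threshold enumeration on
# planted tables instead of the detection pipeline.

# recursive flood-fill connected-component labeling (8- or 4-neighborhood)
flood_fill_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (ci in seq_len(w)) for (ri in seq_len(h)) {
    if (!mask[ri, ci] || lab[ri, ci] > 0L) next
    cur <- cur + 1L
    stack <- list(c(ri, ci))
    lab[ri, ci] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r2 <- p[1] + nb[k, 1]; c2 <- p[2] + nb[k, 2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
              mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# relabel a label matrix canonically (by first pixel in raster scan order)
canonical_labels <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(lab)
  h <- nrow(lab)
  scan <- order(((idx - 1L) %% h) + 1L, ((idx - 1L) %/% h) + 1L)
  seen <- lab[idx][scan]
  relabel <- integer(max(lab))
  relabel[seen[!duplicated(seen)]] <- seq_len(sum(!duplicated(seen)))
  lab[idx] <- relabel[lab[idx]]
  lab
}

# brute-force Mann-Whitney AUC: count all pos/neg pairs, ties as 1/2
brute_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# direct FROC enumeration from per-lesion best scores and per-negative-slide
# false-positive scores
enum_froc_score <- function(lesion_scores, fp_scores, n_neg,
                            fp_rates = c(1/4, 1/2, 1, 2, 4, 8)) {
  thr <- sort(unique(c(lesion_scores[is.finite(lesion_scores)], fp_scores)),
              decreasing = TRUE)
  thr <- c(Inf, thr)
  sens <- sapply(thr, function(t) mean(lesion_scores >= t))
  fp <- sapply(thr, function(t) sum(fp_scores >= t) / n_neg)
  mean(sapply(fp_rates, function(r) {
    ok <- fp <= r
    if (any(ok)) max(sens[ok]) else 0
  }))
}

# small cohort of in-memory slides for sampler/training tests
toy_slides <- function(n_neg = 2, n_pos = 2, dataset = "Toy", seed = 3,
                       extent_mm = 5, micro_only = TRUE) {
  spec <- cohort_spec(dataset, n_negative = n_neg, n_positive = n_pos,
                      slide_extent_mm = extent_mm, raster_spacing_um = 16,
                      micro_fraction = if (micro_only) 1 else 0.6,
                      macro_range_mm = c(2.2, 3), seed = seed)
  lapply(seq_len(n_neg + n_pos), function(i) generate_slide(spec, i))
}

# build a slide_summary straight from planted-truth tables; the independent
# route into the metrics (no detection pipeline involved)
summary_from_planted <- function(records, planted, threshold = 0.5) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    pl <- planted[planted$slide_id == rec$slide_id, , drop = FALSE]
    pl <- pl[pl$score >= threshold, , drop = FALSE]
    les <- pl$score[pl$type == "lesion"]
    fps <- pl$score[pl$type == "fp_blob"]
    positive <- is_positive_label(rec$gt_label)
    tibble::tibble(
      slide_id = rec$slide_id, positive = positive,
      slide_score = if (nrow(pl)) max(pl$score) else 0,
      lesion_scores = list(les),
      fp_scores = list(if (positive) numeric() else fps)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("slide_summary", class(out))
  out
}

# brute-force mining oracle: flood-fill components of {score >= thr}, size
# them, and check pixel overlap against the rasterized ground truth
brute_mine <- function(heatmap, annotations, thr = 0.5, min_d = 0.2) {
  lab <- flood_fill_label(heatmap$scores >= thr, 8)
  gt <- if (!is.null(annotations) && nrow(annotations)) {
    rasterize_polygons(annotations$polygon, dim(heatmap$scores),
                       heatmap$spacing_um)
  } else matrix(FALSE, nrow(heatmap$scores), ncol(heatmap$scores))
  keep <- list()
  for (k in seq_len(max(lab))) {
    px <- which(lab == k)
    props <- region_props(matrix(as.integer(lab == k), nrow(lab)),
                          heatmap$spacing_um)
    if (props$diameter_mm > min_d && !any(gt[px])) {
      keep[[length(keep) + 1L]] <- sort(px)
    }
  }
  keep
}

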