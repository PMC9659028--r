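#' Slide-level area under the ROC curve
#'
#' Computed as the Mann--Whitney statistic over all positive/negative slide
#' pairs, counting ties as one half: the probability that a random positive
#' slide outscores a random negative one.
#'
#' @param scores Numeric slide scores.
#' @param positive Logical ground-truth positivity per slide.
#' @return AUC in `[0, 1]`.
#' @export
slide_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs at least one positive and one negative slide")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-slide sufficient statistics for AUC and FROC
#'
#' Assigns every detection point to the lesion that contains it (point-in-
#' polygon, first match) and condenses each slide to what the metrics need:
#' its slide score, per-lesion best point scores (`-Inf` for a lesion no
#' point hits — a false negative), and the scores of false-positive points
#' (points outside every lesion) on metastasis-free slides. All
#' bootstrap/permutation machinery runs on this summary, so the expensive
#' geometry is done exactly once.
#'
#' @param slides Tibble with `slide_id`, `positive` (logical), and
#'   optionally `slide_score` (else taken as max detection point score, 0 if
#'   none).
#' @param detections Tibble of detection points: `slide_id`, `x_um`, `y_um`,
#'   `score`.
#' @param lesions Tibble of ground-truth lesions: `slide_id`, `lesion_id`,
#'   `polygon` list-column (micrometer vertex matrices). May be empty.
#' @return A `slide_summary` tibble: `slide_id`, `positive`, `slide_score`,
#'   `lesion_scores` and `fp_scores` list-columns.
#' @export
summarize_slides <- function(slides, detections, lesions = NULL) {
  stopifnot(all(c("slide_id", "positive") %in% names(slides)))
  if (is.null(lesions)) {
    lesions <- tibble::tibble(slide_id = character(), lesion_id = integer(),
                              polygon = list())
  }
  rows <- purrr::pmap(slides, function(slide_id, positive, ...) {
    extra <- list(...)
    det <- detections[detections$slide_id == slide_id, , drop = FALSE]
    les <- lesions[lesions$slide_id == slide_id, , drop = FALSE]
    hit <- points_in_polygons(det$x_um, det$y_um, les$polygon)
    lesion_scores <- vapply(seq_len(nrow(les)), function(k) {
      s <- det$score[!is.na(hit) & hit == k]
      if (length(s)) max(s) else -Inf
    }, numeric(1))
    fp_scores <- det$score[is.na(hit)]
    sc <- if (!is.null(extra$slide_score)) extra$slide_score else {
      if (nrow(det)) max(det$score) else 0
    }
    tibble::tibble(
      slide_id = slide_id, positive = as.logical(positive),
      slide_score = sc,
      lesion_scores = list(lesion_scores),
      fp_scores = list(if (positive) numeric() else fp_scores)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("slide_summary", class(out))
  out
}

#' Metric accessors on a slide summary
#'
#' Evaluate the slide-level AUC or the summary FROC score on a subset of a
#' [summarize_slides()] table, addressed by slide indices (with repetition
#' allowed). These are the statistic functions fed to [bootstrap_ci()] and
#' used inside [permutation_test()]; they return `NA` when the subset
#' cannot support the metric (single-class for AUC; no lesion or no
#' metastasis-free slide for FROC).
#'
#' @param summary A `slide_summary` tibble.
#' @param ids Integer slide indices, possibly repeated.
#' @return A number in `[0, 1]`, or `NA`.
#' @export
auc_from_summary <- function(summary, ids = seq_len(nrow(summary))) {
  s <- summary[ids, ]
  if (!any(s$positive) || all(s$positive)) return(NA_real_)
  slide_auc(s$slide_score, s$positive)
}

froc_points_from_summary <- function(summary, ids = seq_len(nrow(summary))) {
  s <- summary[ids, ]
  lesion_scores <- unlist(s$lesion_scores[s$positive])
  fp_scores <- unlist(s$fp_scores[!s$positive])
  n_neg <- sum(!s$positive)
  list(lesion_scores = lesion_scores, fp_scores = fp_scores, n_neg = n_neg)
}

#' Free-response ROC curve at the lesion level
#'
#' Sweeps a score threshold over every distinct detection score and reports,
#' per threshold, the lesion sensitivity (fraction of ground-truth lesions
#' containing at least one retained point; multiple points in one lesion
#' count once) against the average number of retained false-positive points
#' per metastasis-free slide.
#'
#' @param summary A `slide_summary` from [summarize_slides()].
#' @return A `froc_curve` tibble with columns `threshold`,
#'   `fp_per_neg_slide`, `sensitivity`, ordered by decreasing threshold,
#'   starting from the empty operating point `(Inf, 0, 0)`.
#' @export
froc <- function(summary) {
  pts <- froc_points_from_summary(summary)
  if (length(pts$lesion_scores) == 0L) {
    stop("FROC needs at least one ground-truth lesion")
  }
  if (pts$n_neg == 0L) {
    stop("FROC needs at least one metastasis-free slide")
  }
  thr <- sort(unique(c(pts$lesion_scores[is.finite(pts$lesion_scores)],
                       pts$fp_scores)), decreasing = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    fp_per_neg_slide = vapply(c(Inf, thr), function(t) {
      sum(pts$fp_scores >= t) / pts$n_neg
    }, numeric(1)),
    sensitivity = vapply(c(Inf, thr), function(t) {
      mean(pts$lesion_scores >= t)
    }, numeric(1))
  )
  class(curve) <- c("froc_curve", class(curve))
  curve
}

#' Summary FROC score
#'
#' The mean lesion sensitivity at six predefined false-positive rates per
#' slide: 1/4, 1/2, 1, 2, 4 and 8. At each rate the attained sensitivity is
#' the maximum over thresholds whose false-positive rate does not exceed the
#' target (step-function reading, no interpolation); rates beyond the
#' curve's maximum reuse the terminal sensitivity.
#'
#' @param curve A `froc_curve` from [froc()].
#' @param fp_rates The predefined rates.
#' @return FROC score in `[0, 1]`.
#' @export
froc_score <- function(curve, fp_rates = c(1/4, 1/2, 1, 2, 4, 8)) {
  vapply(fp_rates, function(r) {
    ok <- curve$fp_per_neg_slide <= r
    if (any(ok)) max(curve$sensitivity[ok]) else 0
  }, numeric(1)) |> mean()
}

#' @rdname auc_from_summary
#' @export
froc_from_summary <- function(summary, ids = seq_len(nrow(summary))) {
  pts <- froc_points_from_summary(summary, ids)
  if (length(pts$lesion_scores) == 0L || pts$n_neg == 0L) return(NA_real_)
  # inline fast path of froc() + froc_score()
  thr <- sort(unique(c(pts$lesion_scores[is.finite(pts$lesion_scores)],
                       pts$fp_scores)), decreasing = TRUE)
  thr <- c(Inf, thr)
  fp <- vapply(thr, function(t) sum(pts$fp_scores >= t) / pts$n_neg,
               numeric(1))
  sens <- vapply(thr, function(t) mean(pts$lesion_scores >= t), numeric(1))
  mean(vapply(c(1/4, 1/2, 1, 2, 4, 8), function(r) {
    ok <- fp <= r
    if (any(ok)) max(sens[ok]) else 0
  }, numeric(1)))
}

#' Percentile bootstrap confidence interval over slides
#'
#' Resamples slides with replacement and returns the percentile interval of
#' the statistic. Resamples on which the statistic is undefined (e.g. a
#' single-class draw for AUC) are redrawn.
#'
#' @param statistic Function of an integer vector of slide indices (with
#'   repetition) returning a number or `NA` when undefined.
#' @param n_slides Number of slides in the dataset.
#' @param n Number of bootstrap samples (study default 10,000).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List with `lower`, `upper`, `level`, `replicates`.
#' @export
bootstrap_ci <- function(statistic, n_slides, n = 10000, level = 0.95,
                         seed = 1L) {
  stopifnot(n_slides >= 2)
  with_seed(seed, {
    reps <- numeric(n)
    for (b in seq_len(n)) {
      val <- NA_real_
      for (try in 1:1000) {
        ids <- sample.int(n_slides, n_slides, replace = TRUE)
        val <- statistic(ids)
        if (!is.na(val)) break
      }
      if (is.na(val)) stop("statistic undefined on all bootstrap resamples")
      reps[b] <- val
    }
    qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    list(lower = qs[1], upper = qs[2], level = level, replicates = reps)
  })
}

#' Permutation test for a difference in AUC or FROC
#'
#' Tests whether two slide sets (or two models on the same slides) differ in
#' a slide-level statistic. Unpaired mode pools the slides of both groups
#' and permutes the group assignment; paired mode swaps the two models'
#' per-slide predictions with probability one half. The p-value is the
#' add-one-corrected fraction of permuted absolute differences at least as
#' large as the observed one (two-sided). Permutations on which the
#' statistic is undefined in either group are redrawn.
#'
#' @param summary_a,summary_b `slide_summary` tibbles. In paired mode they
#'   must cover the same slides in the same order.
#' @param statistic `"auc"` or `"froc"`.
#' @param n Number of permutations (study default 10,000).
#' @param paired Paired (model-swap) or unpaired (group-shuffle) mode.
#' @param seed Integer seed.
#' @return List with `p_value`, `observed` (observed absolute difference),
#'   `statistic`, `n`.
#' @export
permutation_test <- function(summary_a, summary_b,
                             statistic = c("auc", "froc"),
                             n = 10000, paired = FALSE, seed = 1L) {
  statistic <- match.arg(statistic)
  stat_fn <- if (statistic == "auc") auc_from_summary else froc_from_summary
  obs_a <- stat_fn(summary_a); obs_b <- stat_fn(summary_b)
  if (is.na(obs_a) || is.na(obs_b)) {
    stop("statistic undefined on one of the groups")
  }
  observed <- abs(obs_a - obs_b)
  na <- nrow(summary_a); nb <- nrow(summary_b)
  if (paired && na != nb) stop("paired mode needs equal-size groups")
  pooled <- if (!paired) dplyr::bind_rows(summary_a, summary_b) else NULL
  with_seed(seed, {
    exceed <- 0L
    for (p in seq_len(n)) {
      diff <- NA_real_
      for (try in 1:1000) {
        if (paired) {
          swap <- stats::runif(na) < 0.5
          a <- summary_a; b <- summary_b
          a[swap, ] <- summary_b[swap, ]
          b[swap, ] <- summary_a[swap, ]
          diff <- abs(stat_fn(a) - stat_fn(b))
        } else {
          ids <- sample.int(na + nb, na)
          diff <- abs(stat_fn(pooled, ids) -
                        stat_fn(pooled, setdiff(seq_len(na + nb), ids)))
        }
        if (!is.na(diff)) break
      }
      if (is.na(diff)) stop("statistic undefined on all permutations")
      if (diff >= observed - 1e-12) exceed <- exceed + 1L
    }
    list(p_value = (exceed + 1) / (n + 1), observed = observed,
         statistic = statistic, n = n)
  })
}

#' Evaluate a slide set: AUC and FROC with bootstrap intervals
#'
#' The study's evaluation bundle for one dataset/model: slide-level AUC,
#' lesion-level FROC score, and percentile-bootstrap 95% confidence
#' intervals for both.
#'
#' @param summary A `slide_summary` from [summarize_slides()].
#' @param n_bootstrap Bootstrap samples (study default 10,000).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return An `eval_result` object; see [tidy.eval_result()].
#' @export
evaluate_slides <- function(summary, n_bootstrap = 10000, level = 0.95,
                            seed = 1L) {
  auc <- auc_from_summary(summary)
  fr <- froc_from_summary(summary)
  auc_ci <- bootstrap_ci(function(ids) auc_from_summary(summary, ids),
                         nrow(summary), n = n_bootstrap, level = level,
                         seed = derive_seed(seed, 1L))
  froc_ci <- if (!is.na(fr)) {
    bootstrap_ci(function(ids) froc_from_summary(summary, ids),
                 nrow(summary), n = n_bootstrap, level = level,
                 seed = derive_seed(seed, 2L))
  } else NULL
  structure(
    list(auc = auc, froc = fr,
         auc_ci = c(auc_ci$lower, auc_ci$upper),
         froc_ci = if (!is.null(froc_ci)) c(froc_ci$lower, froc_ci$upper),
         n_bootstrap = n_bootstrap, level = level,
         n_slides = nrow(summary), n_positive = sum(summary$positive)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d slides (%d positive)\n",
              x$n_slides, x$n_positive))
  cat(sprintf("  AUC  %.3f (%.0f%% CI %.3f-%.3f)\n", x$auc, 100 * x$level,
              x$auc_ci[1], x$auc_ci[2]))
  if (!is.null(x$froc)) {
    cat(sprintf("  FROC %.3f (%.0f%% CI %.3f-%.3f)\n", x$froc,
                100 * x$level, x$froc_ci[1], x$froc_ci[2]))
  }
  invisible(x)
}

#' Tidy an evaluation result
#'
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return One row per metric: `metric`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @method tidy eval_result
#' @export
tidy.eval_result <- function(x, ...) {
  tibble::tibble(
    metric = c("auc", "froc"),
    estimate = c(x$auc, ifelse(is.null(x$froc), NA_real_, x$froc)),
    conf.low = c(x$auc_ci[1], ifelse(is.null(x$froc_ci), NA_real_,
                                     x$froc_ci[1])),
    conf.high = c(x$auc_ci[2], ifelse(is.null(x$froc_ci), NA_real_,
                                      x$froc_ci[2]))
  )
}

#' @rdname tidy.eval_result
#' @method glance eval_result
#' @export
glance.eval_result <- function(x, ...) {
  tibble::tibble(n_slides = x$n_slides, n_positive = x$n_positive,
                 auc = x$auc,
                 froc = ifelse(is.null(x$froc), NA_real_, x$froc),
                 n_bootstrap = x$n_bootstrap, conf.level = x$level)
}

#' Plot a FROC curve
#'
#' @param object A `froc_curve`.
#' @param fp_rates Predefined rates drawn as reference lines.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot froc_curve
#' @export
autoplot.froc_curve <- function(object, fp_rates = c(1/4, 1/2, 1, 2, 4, 8),
                                ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$fp_per_neg_slide, .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_vline(xintercept = fp_rates, linetype = 3,
                        color = "grey60") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "false positives per metastasis-free slide",
                  y = "lesion sensitivity")
}
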