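test_that("slide AUC equals brute-force pair counting", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(4:50, 1)
    pos <- c(TRUE, FALSE, runif(n - 2) < 0.5)  # both classes guaranteed
    scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    expect_equal(slide_auc(scores, pos), brute_auc(scores, pos))
  }
  expect_equal(slide_auc(c(0.9, 0.8, 0.3, 0.1),
                         c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(slide_auc(rep(0.4, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE,
                                        FALSE)), 0.5)
  expect_equal(slide_auc(c(0.8, 0.4, 0.6, 0.2),
                         c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(slide_auc(1:3, c(TRUE, TRUE, TRUE)), "at least one")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- runif(40)
  pos <- runif(40) < 0.4
  pos[1:2] <- c(TRUE, FALSE)
  expect_equal(
    slide_auc(scores, pos),
    as.numeric(suppressMessages(pROC::auc(pROC::roc(pos, scores,
                                                    quiet = TRUE)))))
})

# the three-slide FROC example: 2 lesions, one hit at 0.9, FPs at 0.7 and
# 0.6 spread over 2 metastasis-free slides
hand_summary <- function() {
  s <- tibble::tibble(
    slide_id = c("p1", "n1", "n2"),
    positive = c(TRUE, FALSE, FALSE),
    slide_score = c(0.9, 0.7, 0.6),
    lesion_scores = list(c(0.9, -Inf), numeric(), numeric()),
    fp_scores = list(numeric(), 0.7, 0.6)
  )
  class(s) <- c("slide_summary", class(s))
  s
}

test_that("the FROC curve matches hand enumeration", {
  cv <- froc(hand_summary())
  expect_equal(cv$fp_per_neg_slide, c(0, 0, 0.5, 1))
  expect_equal(cv$sensitivity, c(0, 0.5, 0.5, 0.5))
  expect_equal(cv$threshold, c(Inf, 0.9, 0.7, 0.6))
  # FROC score: sensitivity 0.5 attainable at every predefined rate
  expect_equal(froc_score(cv), 0.5)
  expect_equal(froc_score(cv),
               enum_froc_score(c(0.9, -Inf), c(0.7, 0.6), 2))
})

test_that("FROC is monotone and invariant to duplicate points in a lesion", {
  set.seed(12)
  for (rep in 1:20) {
    n_pos <- sample(1:3, 1); n_neg <- sample(1:3, 1)
    rows <- list()
    for (i in seq_len(n_pos)) {
      n_les <- sample(1:4, 1)
      ls <- ifelse(runif(n_les) < 0.3, -Inf, round(runif(n_les), 2))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        slide_id = paste0("p", i), positive = TRUE,
        slide_score = max(c(ls[is.finite(ls)], 0)),
        lesion_scores = list(ls), fp_scores = list(numeric()))
    }
    for (i in seq_len(n_neg)) {
      fp <- round(runif(sample(0:4, 1)), 2)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        slide_id = paste0("n", i), positive = FALSE,
        slide_score = max(c(fp, 0)),
        lesion_scores = list(numeric()), fp_scores = list(fp))
    }
    s <- dplyr::bind_rows(rows)
    class(s) <- c("slide_summary", class(s))
    cv <- froc(s)
    expect_true(all(diff(cv$fp_per_neg_slide) >= 0))
    expect_true(all(diff(cv$sensitivity) >= 0))
    expect_equal(
      froc_score(cv),
      enum_froc_score(unlist(s$lesion_scores[s$positive]),
                      unlist(s$fp_scores[!s$positive]), n_neg))
  }
})

test_that("degenerate FROC inputs raise errors", {
  s <- hand_summary()
  expect_error(froc(s[1, ]), "metastasis-free")
  expect_error(froc(s[2:3, ]), "lesion")
})

test_that("summarize_slides assigns points to lesions and FPs correctly", {
  lesions <- tibble::tibble(
    slide_id = c("a", "a"), lesion_id = 1:2,
    polygon = list(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)),
                   cbind(c(200, 300, 300, 200), c(0, 0, 100, 100))))
  detections <- tibble::tibble(
    slide_id = c("a", "a", "a", "b"),
    x_um = c(50, 60, 250, 40), y_um = c(50, 60, 50, 40),
    score = c(0.9, 0.95, 0.6, 0.3))
  slides <- tibble::tibble(slide_id = c("a", "b"),
                           positive = c(TRUE, FALSE))
  s <- summarize_slides(slides, detections, lesions)
  expect_equal(s$lesion_scores[[1]], c(0.95, 0.6))  # best point per lesion
  expect_equal(s$fp_scores[[2]], 0.3)
  expect_equal(s$slide_score, c(0.95, 0.3))
})

test_that("bootstrap intervals: constant statistic, determinism, ordering", {
  ci <- bootstrap_ci(function(ids) 0.7, n_slides = 10, n = 200, seed = 4)
  expect_equal(ci$lower, 0.7)
  expect_equal(ci$upper, 0.7)
  s <- hand_summary()
  f <- function(ids) auc_from_summary(s, ids)
  c1 <- bootstrap_ci(f, 3, n = 300, seed = 9)
  c2 <- bootstrap_ci(f, 3, n = 300, seed = 9)
  expect_identical(c1, c2)
  expect_lte(c1$lower, c1$upper)
  expect_true(c1$lower >= 0 && c1$upper <= 1)
})

test_that("permutation test: identical groups give p near 1, small cases
           match exhaustive enumeration", {
  s <- hand_summary()
  same <- permutation_test(s, s, "auc", n = 300, seed = 2)
  expect_gt(same$p_value, 0.9)

  # 3 vs 3 slides with distinct scores: enumerate all C(6,3) assignments
  mk <- function(scores, pos) {
    t <- tibble::tibble(slide_id = paste0("s", seq_along(scores), pos[1],
                                          scores),
                        positive = pos, slide_score = scores,
                        lesion_scores = replicate(length(scores),
                                                  numeric(), simplify = FALSE),
                        fp_scores = replicate(length(scores), numeric(),
                                              simplify = FALSE))
    class(t) <- c("slide_summary", class(t))
    t
  }
  a <- mk(c(0.9, 0.8, 0.2), c(TRUE, TRUE, FALSE))
  b <- mk(c(0.5, 0.3, 0.6), c(TRUE, FALSE, FALSE))
  pooled <- dplyr::bind_rows(a, b)
  obs <- abs(auc_from_summary(a) - auc_from_summary(b))
  combos <- utils::combn(6, 3)
  diffs <- apply(combos, 2, function(ids) {
    abs_diff <- tryCatch({
      abs(auc_from_summary(pooled, ids) -
            auc_from_summary(pooled, setdiff(1:6, ids)))
    }, error = function(e) NA_real_)
    abs_diff
  })
  valid <- diffs[!is.na(diffs)]
  p_exact <- mean(valid >= obs - 1e-12)
  p_mc <- permutation_test(a, b, "auc", n = 4000, seed = 7)$p_value
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000) +
              1 / 4000)
})

test_that("paired permutation swaps per-slide predictions", {
  mk <- function(scores) {
    t <- tibble::tibble(slide_id = paste0("s", seq_along(scores)),
                        positive = rep(c(TRUE, FALSE), length.out =
                                         length(scores)),
                        slide_score = scores,
                        lesion_scores = replicate(length(scores), numeric(),
                                                  simplify = FALSE),
                        fp_scores = replicate(length(scores), numeric(),
                                              simplify = FALSE))
    class(t) <- c("slide_summary", class(t))
    t
  }
  a <- mk(c(0.9, 0.1, 0.85, 0.2, 0.95, 0.15))
  pt <- permutation_test(a, a, "auc", n = 100, paired = TRUE, seed = 3)
  expect_equal(pt$observed, 0)
  expect_equal(pt$p_value, 1)
  expect_error(permutation_test(a, a[1:4, ], "auc", paired = TRUE),
               "equal-size")
})

test_that("evaluate_slides bundles metrics with intervals; broom methods", {
  s <- hand_summary()
  res <- evaluate_slides(s, n_bootstrap = 200, seed = 5)
  expect_s3_class(res, "eval_result")
  expect_equal(res$auc, 1)
  expect_equal(res$froc, 0.5)
  td <- tidy(res)
  expect_equal(td$metric, c("auc", "froc"))
  expect_true(all(td$conf.low <= td$estimate | is.na(td$conf.low)))
  gl <- glance(res)
  expect_equal(gl$n_slides, 3)
  expect_equal(gl$n_bootstrap, 200)
  expect_s3_class(autoplot(froc(s)), "ggplot")
})
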