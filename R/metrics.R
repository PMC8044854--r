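# Evaluation metrics: confusion counts, per-class precision/recall/F1,
# class-size-weighted F1, paired t-test and Bonferroni adjustment.

#' Confusion counts for a designated positive class
#'
#' @param predicted,truth Equal-length label vectors (two classes).
#' @param positive The class treated as positive.
#' @return A tibble with `TP`, `FP`, `TN`, `FN` (summing to the sample count).
#' @export
confusion_counts <- function(predicted, truth, positive = "positive") {
  assert_that(length(predicted) == length(truth),
              "predicted and truth must have equal length")
  p <- predicted == positive
  t <- truth == positive
  tibble::tibble(TP = sum(p & t), FP = sum(p & !t),
                 TN = sum(!p & !t), FN = sum(!p & t))
}

#' Precision, recall and F1 from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R).
#' Undefined 0/0 ratios are reported as 0 with `degenerate = TRUE`.
#'
#' @param counts One-row tibble/list with `TP`, `FP`, `TN`, `FN`.
#' @return A tibble: `precision`, `recall`, `f1`, `degenerate`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  degen <- FALSE
  ratio0 <- function(num, den) {
    if (den == 0) { degen <<- TRUE; 0 } else num / den
  }
  precision <- ratio0(tp, tp + fp)
  recall <- ratio0(tp, tp + fn)
  f1 <- ratio0(2 * precision * recall, precision + recall)
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 degenerate = degen)
}

#' Per-class metrics, each class treated as positive in turn
#'
#' @param predicted,truth Equal-length label vectors.
#' @param classes The two class labels.
#' @return A tibble with one row per class: `class`, `precision`, `recall`,
#'   `f1`, `n` (true class size), `degenerate`.
#' @export
class_metrics <- function(predicted, truth, classes = CLASS_LEVELS) {
  dplyr::bind_rows(lapply(classes, function(cl) {
    cc <- confusion_counts(predicted, truth, positive = cl)
    m <- precision_recall_f1(cc)
    m$class <- cl
    m$n <- sum(truth == cl)
    m
  }))[, c("class", "precision", "recall", "f1", "n", "degenerate")]
}

#' Class-size-weighted F1
#'
#' `(N+ * F1+ + N- * F1-) / (N+ + N-)` -- the mean of the per-class F1 scores
#' weighted by the true class sizes.
#'
#' @param f1 Per-class F1 scores.
#' @param n Per-class true counts (not all zero).
#' @return A single number in `[0, 1]`.
#' @export
weighted_f1 <- function(f1, n) {
  assert_that(length(f1) == length(n) && all(n >= 0), "invalid class counts")
  assert_that(sum(n) > 0, "at least one class must be populated")
  sum(n * f1) / sum(n)
}

#' Full metric set for one evaluation
#'
#' @param predicted,truth Equal-length label vectors.
#' @return One-row tibble: per-class precision/recall/F1/N (suffixes
#'   `_positive`, `_negative`), `weighted_f1`, `accuracy`.
#' @export
evaluate_predictions <- function(predicted, truth) {
  cm <- class_metrics(predicted, truth)
  wide <- tidyr::pivot_wider(cm[, c("class", "precision", "recall", "f1", "n")],
                             names_from = "class",
                             values_from = c("precision", "recall", "f1", "n"))
  wide$weighted_f1 <- weighted_f1(cm$f1, cm$n)
  wide$accuracy <- mean(predicted == truth)
  wide
}

#' Paired t-test on fold-wise scores
#'
#' Classical paired t on the per-fold differences (df = n - 1). If every
#' difference is identical: zero mean reports `t = 0, p = 1`; nonzero mean
#' reports `t = +/-Inf, p = 0`.
#'
#' @param scores_a,scores_b Equal-length paired score vectors (n >= 2).
#' @return A tibble: `estimate` (mean difference), `t`, `df`, `p_value`.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  assert_that(length(scores_a) == length(scores_b) && length(scores_a) >= 2,
              "need equal-length paired vectors with n >= 2")
  d <- scores_a - scores_b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(estimate = 0, t = 0, df = n - 1, p_value = 1))
    }
    return(tibble::tibble(estimate = mean(d), t = sign(mean(d)) * Inf,
                          df = n - 1, p_value = 0))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
}

#' Bonferroni adjustment
#'
#' @param p Raw p values.
#' @param m Number of simultaneous comparisons (default `length(p)`).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  assert_that(m >= 1, "m must be >= 1")
  pmin(1, m * p)
}
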