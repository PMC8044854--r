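# Channel-ablation experiment: 7 channel combinations x {FCN, PCA-SVM},
# 5-fold cross-validation with a 20% hold-out, paired model comparison.

#' Build a labeled cell-image dataset from synthetic micrographs
#'
#' Generates `n_stacks` seeded micrographs, runs the full preprocessing
#' pipeline on each (using the ground-truth component mask as the external
#' segmentation, as a stand-in for the external segmenter), annotates crops
#' with the true class and concatenates everything with globally unique cell
#' ids.
#'
#' @param n_stacks Number of micrographs.
#' @param config A [synth_config()]; its seed is re-derived per stack.
#' @param preprocess A [preprocess_config()].
#' @param seed Base seed.
#' @param drop_unknown Drop crops that cannot be matched to a true cell.
#' @return A `gad_cells` object whose `crops` tibble spans all stacks.
#' @export
build_synthetic_dataset <- function(n_stacks = 6,
                                    config = synth_config(),
                                    preprocess = preprocess_config(),
                                    seed = 1,
                                    drop_unknown = TRUE) {
  crops <- list(); rois <- list(); stats <- list()
  offset <- 0L
  channels <- NULL
  for (s in seq_len(n_stacks)) {
    cfg <- config
    cfg$seed <- as.integer(derive_seed(seed, s) %% 2147483647)
    sim <- generate_micrograph(cfg)
    pp <- preprocess_micrograph(sim$stack, masks = sim$truth$label_mask,
                                truth = sim$truth, config = preprocess)
    cr <- pp$crops
    cr$stack <- s
    cr$cell_id <- cr$cell_id + offset
    if (nrow(cr) > 0) offset <- max(cr$cell_id)
    crops[[s]] <- cr
    rois[[s]] <- pp$rois
    st <- pp$stats
    st$stack <- s
    stats[[s]] <- st
    channels <- pp$channels
  }
  crops <- dplyr::bind_rows(crops)
  if (drop_unknown) crops <- dplyr::filter(crops, .data$label != "unknown")
  attr(crops, "channels") <- channels
  structure(list(crops = crops, rois = dplyr::bind_rows(rois),
                 stats = dplyr::bind_rows(stats), channels = channels),
            class = "gad_cells")
}

#' Run the channel-ablation experiment
#'
#' For every requested channel combination and model: 5-fold cross-validation
#' over the non-hold-out cells (train on four segments -- majority class
#' downsampled with compensatory weights for the FCN, balanced class weights
#' for the SVM -- checkpoint on the fifth), then scoring on both the fold's
#' test segment and the untouched 20% hold-out, which keeps the natural class
#' ratio.
#'
#' @param crops Labeled cell-image tibble (or a `gad_cells`).
#' @param combos List of channel combinations (default: all seven).
#' @param models Character subset of `c("fcn", "pca_svm")`.
#' @param config A [train_config()] for the FCN.
#' @param fold_plan Optional precomputed [make_fold_plan()].
#' @param fcn_features Feature-map counts of the FCN blocks.
#' @param seed Base seed for fold plan, balancing and training.
#' @param verbose Print one line per (combo, model, fold).
#' @return A metric-report tibble: one row per (model, combo, fold, eval_set)
#'   with per-class precision/recall/F1/N and `weighted_f1`.
#' @export
run_experiment <- function(crops,
                           combos = channel_combos(),
                           models = c("fcn", "pca_svm"),
                           config = train_config(epochs = 50),
                           fold_plan = NULL,
                           fcn_features = c(16, 32, 64),
                           seed = 1,
                           verbose = FALSE) {
  if (inherits(crops, "gad_cells")) crops <- crops$crops
  assert_that(all(models %in% c("fcn", "pca_svm")), "unknown model tag")
  assert_that(all(crops$label %in% CLASS_LEVELS),
              "crops must be labeled positive/negative")
  plan <- fold_plan %||% make_fold_plan(crops$cell_id, seed = seed)
  n_folds <- attr(plan, "n_folds") %||% 5
  ch_attr <- attr(crops, "channels")
  crops <- dplyr::left_join(crops, plan, by = "cell_id")
  attr(crops, "channels") <- ch_attr
  assert_that(!anyNA(crops$split), "fold plan does not cover all cells")
  reports <- list()
  for (combo in combos) {
    sel <- select_channels(crops, combo)
    attr_ch <- attr(sel, "channels")
    for (f in seq_len(n_folds)) {
      fold_tag <- paste0("fold-", f)
      train <- sel[!(sel$split %in% c("validation", fold_tag)), , drop = FALSE]
      test <- sel[sel$split == fold_tag, , drop = FALSE]
      val <- sel[sel$split == "validation", , drop = FALSE]
      attr(train, "channels") <- attr_ch
      attr(test, "channels") <- attr_ch
      attr(val, "channels") <- attr_ch
      for (mdl in models) {
        if (verbose) {
          message(sprintf("[%s] %s fold %d", combo_label(combo), mdl, f))
        }
        run_seed <- derive_seed(seed, 1000 * f + match(mdl, c("fcn", "pca_svm")))
        if (mdl == "fcn") {
          bal <- balance_downsample(train, seed = run_seed)
          cfg <- config
          cfg$seed <- as.integer(run_seed %% 2147483647)
          fit <- train_fcn(bal$records, test, config = cfg,
                           spec = fcn_spec(length(combo), features = fcn_features))
          pred_val <- predict(fit, val)$.pred_class
          pred_test <- predict(fit, test)$.pred_class
          extra <- tibble::tibble(checkpoint_epoch = fit$checkpoint_epoch)
        } else {
          fit <- train_pca_svm(train)
          pred_val <- predict(fit, val)$.pred_class
          pred_test <- predict(fit, test)$.pred_class
          extra <- tibble::tibble(checkpoint_epoch = NA_integer_)
        }
        for (es in c("holdout", "test_segment")) {
          truth <- if (es == "holdout") val$label else test$label
          pred <- if (es == "holdout") pred_val else pred_test
          row <- evaluate_predictions(pred, truth)
          row$model <- mdl
          row$combo <- combo_label(combo)
          row$fold <- f
          row$eval_set <- es
          row$seed <- seed
          row <- dplyr::bind_cols(row, extra)
          reports[[length(reports) + 1]] <- row
        }
      }
    }
  }
  out <- dplyr::bind_rows(reports)
  dplyr::relocate(out, "model", "combo", "fold", "eval_set")
}

#' Summarize a metric report per model and combination
#'
#' @param report Output of [run_experiment()].
#' @param eval_set Which evaluation set to summarize.
#' @param metric Metric column to summarize.
#' @return Tibble: model, combo, n folds, mean and SD of the metric.
#' @export
summarize_report <- function(report, eval_set = "holdout",
                             metric = "weighted_f1") {
  dat <- report[report$eval_set == eval_set, , drop = FALSE]
  dplyr::summarize(dplyr::group_by(dat, .data$model, .data$combo),
                   n = dplyr::n(),
                   mean = mean(.data[[metric]]),
                   sd = stats::sd(.data[[metric]]),
                   .groups = "drop")
}

#' Paired comparison of the two models per channel combination
#'
#' Paired t-test on fold-wise weighted F1 (FCN vs PCA-SVM), Bonferroni
#' adjusted over the number of combinations compared.
#'
#' @param report Output of [run_experiment()] containing both models.
#' @param eval_set Which evaluation set to compare on.
#' @param metric Metric column.
#' @param m Bonferroni multiplier (default: number of combos in the report).
#' @return Tibble per combo: means, fold wins, t, df, raw and adjusted p,
#'   significance flag at 0.05.
#' @export
compare_models <- function(report, eval_set = "holdout",
                           metric = "weighted_f1", m = NULL) {
  dat <- report[report$eval_set == eval_set, , drop = FALSE]
  combos <- unique(dat$combo)
  m <- m %||% length(combos)
  rows <- lapply(combos, function(cb) {
    a <- dat[dat$combo == cb & dat$model == "fcn", , drop = FALSE]
    b <- dat[dat$combo == cb & dat$model == "pca_svm", , drop = FALSE]
    a <- a[order(a$fold), , drop = FALSE]
    b <- b[order(b$fold), , drop = FALSE]
    tt <- paired_t_test(a[[metric]], b[[metric]])
    tibble::tibble(combo = cb,
                   mean_fcn = mean(a[[metric]]), mean_svm = mean(b[[metric]]),
                   fcn_wins = sum(a[[metric]] > b[[metric]]),
                   n_folds = nrow(a),
                   t = tt$t, df = tt$df, p_value = tt$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bonferroni_adjust(out$p_value, m = m)
  out$significant <- out$p_adjusted < 0.05
  out
}

#' Channel-ablation plot of a metric report
#'
#' Fold-wise points and per-condition means, by model and channel
#' combination.
#'
#' @param report Output of [run_experiment()].
#' @param eval_set Which evaluation set to plot.
#' @param metric Metric column.
#' @return A ggplot object.
#' @export
plot_ablation <- function(report, eval_set = "holdout",
                          metric = "weighted_f1") {
  dat <- report[report$eval_set == eval_set, , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$combo, y = .data[[metric]],
                                    color = .data$model)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = NULL, y = metric, color = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Class-wise histograms of ROI statistics
#'
#' Mirrors the usual per-channel fluorescence / area / circularity summaries:
#' overlapping per-class histograms of one ROI statistic.
#'
#' @param stats ROI statistics tibble with a `label` column.
#' @param feature Column to plot (e.g. `"mean_GAD67"`, `"area"`,
#'   `"circularity"`).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_roi_histograms <- function(stats, feature, bins = 40) {
  dat <- stats[stats$label %in% CLASS_LEVELS, , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[feature]], fill = .data$label)) +
    ggplot2::geom_histogram(alpha = 0.5, bins = bins, position = "identity") +
    ggplot2::labs(x = feature, y = "ROI count", fill = NULL)
}
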