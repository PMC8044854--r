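# Conventional baseline: flatten + zero-pad crops, PCA retaining >= 95% of
# the variance, RBF-SVM with C = 1, balanced class weights and a computed
# kernel coefficient.

#' Flatten cell images into fixed-length feature rows
#'
#' Each crop is flattened row-major per channel, channels concatenated, and
#' zero-padded to the maximum length seen in the *training* set. When
#' `length` is supplied (transforming validation data), longer rows are
#' truncated with a warning -- validation crops never influence the feature
#' length.
#'
#' @param images Cell-image tibble or list of `h x w x ch` arrays.
#' @param length Target row length; default: the maximum over `images`.
#' @return A numeric matrix (one row per image) with attribute `length`.
#' @export
flatten_and_pad <- function(images, length = NULL) {
  tbl <- as_cellimage_tbl(images)
  assert_that(nrow(tbl) > 0, "no images to flatten")
  flat <- lapply(tbl$crop, function(a) as.numeric(aperm(a, c(2, 1, 3))))
  lens <- lengths(flat)
  L <- length %||% max(lens)
  if (any(lens > L)) {
    warn(sprintf("%d image(s) exceed the training feature length and were truncated",
                 sum(lens > L)))
  }
  X <- matrix(0, nrow = base::length(flat), ncol = L)
  for (i in seq_along(flat)) {
    k <- min(lens[i], L)
    X[i, seq_len(k)] <- flat[[i]][seq_len(k)]
  }
  attr(X, "length") <- L
  X
}

#' RBF kernel coefficient
#'
#' `gamma = 1 / (n_dims * sample_variance)`, with the variance taken over all
#' entries of the training feature matrix (the features handed to the SVM).
#'
#' @param n_dims Number of feature dimensions.
#' @param sample_variance Variance of all feature-matrix entries.
#' @return The kernel coefficient (positive scalar).
#' @export
compute_gamma <- function(n_dims, sample_variance) {
  assert_that(n_dims >= 1, "n_dims must be >= 1")
  assert_that(is.finite(sample_variance) && sample_variance > 0,
              "sample variance must be positive")
  1 / (n_dims * sample_variance)
}

#' Fit a PCA retaining the minimal >= 95%-variance prefix
#'
#' Fitted on the training rows only; validation data must be transformed with
#' the same fit (see [project_pca()]).
#'
#' @param x Training feature matrix (>= 2 rows).
#' @param variance_threshold Cumulative explained-variance target.
#' @return An object of class `gad_pca`: rotation, center, per-component
#'   explained-variance ratios, `n_components`.
#' @export
fit_pca <- function(x, variance_threshold = 0.95) {
  assert_that(nrow(x) >= 2, "PCA needs at least two rows")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  tot <- sum(ev)
  assert_that(tot > 0, "degenerate input: all rows identical")
  ratio <- ev / tot
  k <- which(cumsum(ratio) >= variance_threshold)[1]
  structure(list(rotation = p$rotation[, seq_len(k), drop = FALSE],
                 center = p$center,
                 explained_ratio = ratio,
                 n_components = k,
                 variance_threshold = variance_threshold),
            class = "gad_pca")
}

#' Project features with a fitted PCA
#' @param pca A `gad_pca`.
#' @param x Feature matrix with the same column count as the training data.
#' @return The projected matrix (n x n_components).
#' @export
project_pca <- function(pca, x) {
  sweep(x, 2, pca$center) %*% pca$rotation
}

#' Tidy a fitted PCA: per-component explained variance
#' @param x A `gad_pca`.
#' @param ... Unused.
#' @return Tibble: component, explained-variance ratio, cumulative ratio,
#'   retained flag.
#' @export
tidy.gad_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained_ratio),
                 explained_ratio = x$explained_ratio,
                 cumulative = cumsum(x$explained_ratio),
                 retained = seq_along(x$explained_ratio) <= x$n_components)
}

#' SVM configuration of the baseline
#'
#' RBF kernel, regularization parameter `C = 1`, balanced class weights
#' (inversely proportional to class frequency); gamma is computed from the
#' data by [compute_gamma()], not tuned.
#'
#' @param C Regularization parameter.
#' @param gamma Optional fixed kernel coefficient; `NULL` = computed.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(C = 1, gamma = NULL) {
  structure(list(kernel = "radial", C = C, class_weight = "balanced",
                 gamma = gamma), class = "svm_config")
}

#' Train the RBF-SVM on projected features
#'
#' @param x Projected (post-PCA) training features.
#' @param labels Character/factor labels (`"positive"`/`"negative"`), both
#'   classes present.
#' @param config An [svm_config()].
#' @return A list of class `gad_svm`: the e1071 fit, gamma, class weights.
#' @export
train_svm <- function(x, labels, config = svm_config()) {
  y <- factor(labels, levels = CLASS_LEVELS)
  assert_that(all(table(y) > 0), "both classes must be present")
  gamma <- config$gamma %||% compute_gamma(ncol(x), stats::var(as.numeric(x)))
  n <- length(y)
  cw <- n / (2 * table(y))
  fit <- e1071::svm(x = x, y = y, kernel = "radial", cost = config$C,
                    gamma = gamma, class.weights = setNames(as.numeric(cw), names(cw)),
                    scale = FALSE)
  structure(list(fit = fit, gamma = gamma,
                 class_weights = setNames(as.numeric(cw), names(cw))),
            class = "gad_svm")
}

#' Predict labels from a trained SVM
#' @param svm A `gad_svm`.
#' @param x Projected feature matrix.
#' @return Character vector of labels.
#' @export
predict_svm <- function(svm, x) {
  as.character(predict(svm$fit, x))
}

#' Train the full PCA-SVM baseline on cell images
#'
#' Flatten + pad to the training maximum, fit PCA on the training rows
#' (minimal prefix explaining >= 95% of variance), compute gamma on the
#' projected training matrix, and fit the weighted RBF-SVM. The returned
#' object transforms new images with the same padding length and PCA fit.
#'
#' @param train Labeled cell-image tibble.
#' @param config An [svm_config()].
#' @param variance_threshold PCA explained-variance target.
#' @return An object of class `gad_pca_svm`.
#' @export
train_pca_svm <- function(train, config = svm_config(),
                          variance_threshold = 0.95) {
  X <- flatten_and_pad(train)
  pca <- fit_pca(X, variance_threshold)
  Z <- project_pca(pca, X)
  svm <- train_svm(Z, train$label, config)
  structure(list(pca = pca, svm = svm, feature_length = attr(X, "length"),
                 config = config),
            class = "gad_pca_svm")
}

#' @export
#' @rdname train_pca_svm
#' @param object A `gad_pca_svm`.
#' @param images Cell-image tibble or list of arrays.
#' @param ... Unused.
predict.gad_pca_svm <- function(object, images, ...) {
  X <- flatten_and_pad(images, length = object$feature_length)
  Z <- project_pca(object$pca, X)
  tibble::tibble(.pred_class = predict_svm(object$svm, Z))
}

#' One-row summary of a fitted PCA-SVM baseline
#' @param x A `gad_pca_svm`.
#' @param ... Unused.
#' @return Tibble: feature length, retained components, gamma, C.
#' @export
glance.gad_pca_svm <- function(x, ...) {
  tibble::tibble(feature_length = x$feature_length,
                 n_components = x$pca$n_components,
                 gamma = x$svm$gamma,
                 C = x$config$C)
}
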