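# Fully convolutional classifier: R-side specification, training driver and
# prediction interface over the compiled core.

#' Architecture specification for the fully convolutional classifier
#'
#' Three blocks of convolution -> batch normalization -> ReLU -> dropout,
#' 2x2 max pooling after blocks 1-2 (optional), global max pooling, and a
#' 2-way softmax head. There is no fully connected hidden layer, so inputs of
#' any spatial size are accepted and the parameter count is independent of
#' image size.
#'
#' @param n_channels Number of input fluorescence channels (1-3).
#' @param features Feature-map counts of the three blocks.
#' @param kernel Odd convolution kernel size (same padding).
#' @param dropout Dropout rate inside each block.
#' @param inner_pool Apply 2x2 max pooling after blocks 1 and 2 (global max
#'   pooling at the end is always applied).
#' @return A list of class `fcn_spec`.
#' @export
fcn_spec <- function(n_channels, features = c(16, 32, 64), kernel = 3,
                     dropout = 0.25, inner_pool = TRUE) {
  assert_that(n_channels >= 1 && n_channels <= 3,
              "n_channels must be between 1 and 3")
  assert_that(length(features) == 3 && all(features >= 1),
              "exactly three convolutional blocks are required")
  assert_that(kernel %% 2 == 1, "kernel size must be odd")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(n_channels = as.integer(n_channels),
                 features = as.integer(features), kernel = as.integer(kernel),
                 dropout = dropout, inner_pool = isTRUE(inner_pool)),
            class = "fcn_spec")
}

#' Training configuration
#'
#' Adam (learning rate 0.001, beta1 0.9, beta2 0.999, epsilon 1e-7) or plain
#' SGD (learning rate 0.0001, momentum 0). The loss is class-weighted 2-class
#' cross-entropy; training runs for `epochs` epochs with model checkpointing
#' at the minimum validation loss.
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate Defaults to 0.001 (Adam) or 0.0001 (SGD).
#' @param beta1,beta2,epsilon Adam moment-decay rates and stabilizer.
#' @param momentum SGD momentum.
#' @param epochs Number of training epochs (>= 1; default 500).
#' @param batch_size Batch size (default 8).
#' @param seed Integer seed covering weight init, shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = NULL,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         momentum = 0, epochs = 500, batch_size = 8, seed = 1) {
  optimizer <- match.arg(optimizer)
  learning_rate <- learning_rate %||% if (optimizer == "adam") 0.001 else 0.0001
  assert_that(learning_rate > 0, "learning_rate must be positive")
  assert_that(epochs >= 1, "epochs must be >= 1")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Build (initialize) a fully convolutional classifier
#'
#' He-normal convolution weights, unit batch-norm scale, zero shift; weights
#' are fully determined by the seed.
#'
#' @param spec An [fcn_spec()].
#' @param seed Integer seed for the initialization.
#' @return A model object of class `gad_fcn`.
#' @export
build_fcn <- function(spec, seed = 1) {
  assert_that(inherits(spec, "fcn_spec"), "spec must be an fcn_spec")
  set.seed(seed)
  k2 <- spec$kernel^2
  cins <- c(spec$n_channels, spec$features[1], spec$features[2])
  conv_w <- lapply(1:3, function(l) {
    fan_in <- k2 * cins[l]
    matrix(rnorm(spec$features[l] * fan_in, 0, sqrt(2 / fan_in)),
           spec$features[l], fan_in)
  })
  f3 <- spec$features[3]
  params <- list(
    conv_w = conv_w,
    bn_gamma = lapply(spec$features, function(f) rep(1, f)),
    bn_beta = lapply(spec$features, function(f) rep(0, f)),
    bn_rmean = lapply(spec$features, function(f) rep(0, f)),
    bn_rvar = lapply(spec$features, function(f) rep(1, f)),
    out_w = matrix(rnorm(2 * f3, 0, sqrt(2 / (f3 + 2))), 2, f3),
    out_b = rep(0, 2),
    kernel = spec$kernel,
    inner_pool = spec$inner_pool)
  structure(list(spec = spec, params = params, trained = FALSE,
                 history = NULL, checkpoint_epoch = NA_integer_, seed = seed),
            class = "gad_fcn")
}

#' Number of trainable parameters of a model
#' @param model A `gad_fcn`.
#' @return Integer count (independent of input image size).
#' @export
n_parameters <- function(model) {
  p <- model$params
  sum(vapply(p$conv_w, length, numeric(1))) +
    2 * sum(model$spec$features) +  # gamma + beta
    length(p$out_w) + length(p$out_b)
}

#' Forward pass: class probabilities for cell images
#'
#' Evaluation mode (dropout off, batch normalization uses running statistics).
#' Images may have arbitrary spatial sizes.
#'
#' @param model A `gad_fcn`.
#' @param images Cell-image tibble (list-column `crop`) or a bare list of
#'   `h x w x ch` arrays.
#' @param batch_size Evaluation batch size.
#' @return A numeric matrix (n x 2) with columns `negative`, `positive`;
#'   rows sum to 1.
#' @export
fcn_forward <- function(model, images, batch_size = 8) {
  tbl <- as_cellimage_tbl(images)
  nc <- dim(tbl$crop[[1]])[3]
  assert_that(nc == model$spec$n_channels,
              sprintf("channel mismatch: model expects %d, images have %d",
                      model$spec$n_channels, nc))
  batches <- make_batches(tbl, batch_size = batch_size, shuffle = FALSE)
  probs <- cpp_fcn_forward(model$params, lapply(batches, `[[`, "x"))
  colnames(probs) <- CLASS_LEVELS
  probs
}

as_cellimage_tbl <- function(images) {
  if (is.data.frame(images)) return(images)
  if (is.list(images)) {
    out <- tibble::tibble(crop = images)
    return(out)
  }
  abort("images must be a tibble with a 'crop' column or a list of arrays")
}

#' Train the fully convolutional classifier
#'
#' Minimizes sample-weighted 2-class cross-entropy for `config$epochs` epochs,
#' recording training and validation loss/accuracy each epoch, and returns
#' the checkpointed weights of the epoch with the lowest validation loss.
#' Fully seeded: weight initialization, batch shuffling and dropout.
#'
#' @param train Cell-image tibble with `label` (both classes present) and
#'   optionally `sample_weight`.
#' @param test Cell-image tibble used for per-epoch validation loss (the
#'   checkpointing signal).
#' @param config A [train_config()].
#' @param spec An [fcn_spec()]; inferred from the data when `NULL`.
#' @return A trained `gad_fcn` with `history` tibble and `checkpoint_epoch`.
#' @export
train_fcn <- function(train, test, config = train_config(), spec = NULL) {
  assert_that(nrow(train) > 0 && nrow(test) > 0,
              "training and test sets must be nonempty")
  assert_that(length(unique(train$label)) == 2,
              "training set must contain both classes")
  nc <- dim(train$crop[[1]])[3]
  spec <- spec %||% fcn_spec(n_channels = nc)
  assert_that(spec$n_channels == nc, "spec channel count does not match data")
  model <- build_fcn(spec, seed = config$seed)
  # batches are re-drawn from a fresh seeded shuffle every epoch inside the
  # compiled trainer, zero-padded to the largest crop in each batch
  test_b <- make_batches(test, batch_size = config$batch_size, shuffle = FALSE)
  set.seed(derive_seed(config$seed, 2))
  cpp_seed <- sample.int(2147483646, 1)
  opts <- list(epochs = config$epochs, optimizer = config$optimizer,
               learning_rate = config$learning_rate, beta1 = config$beta1,
               beta2 = config$beta2, epsilon = config$epsilon,
               momentum = config$momentum, dropout = spec$dropout,
               seed = as.double(cpp_seed))
  w <- if ("sample_weight" %in% names(train)) train$sample_weight else rep(1, nrow(train))
  fit <- cpp_fcn_train(model$params,
                       train$crop, as.integer(train$label == "positive"),
                       as.numeric(w), config$batch_size,
                       lapply(test_b, `[[`, "x"), lapply(test_b, `[[`, "y"),
                       lapply(test_b, `[[`, "w"),
                       opts)
  hist <- tibble::tibble(
    epoch = seq_len(config$epochs),
    loss = fit$history[, 1], accuracy = fit$history[, 2],
    val_loss = fit$history[, 3], val_accuracy = fit$history[, 4])
  model$params <- fit$best_params
  model$final_params <- fit$final_params
  model$trained <- TRUE
  model$history <- hist
  model$checkpoint_epoch <- fit$checkpoint_epoch
  model$best_val_loss <- fit$best_val_loss
  model$config <- config
  model
}

#' Predict class labels for cell images
#'
#' Labels are the argmax of the softmax output; exact ties go to the
#' negative class.
#'
#' @param object A `gad_fcn`.
#' @param images Cell-image tibble or list of arrays.
#' @param ... Unused.
#' @return A tibble: `.pred_class`, `.pred_negative`, `.pred_positive`.
#' @export
predict.gad_fcn <- function(object, images, ...) {
  probs <- fcn_forward(object, images)
  tibble::tibble(
    .pred_class = unname(ifelse(probs[, "positive"] > probs[, "negative"],
                                "positive", "negative")),
    .pred_negative = unname(probs[, "negative"]),
    .pred_positive = unname(probs[, "positive"]))
}

#' Weighted cross-entropy loss and accuracy of a model on a dataset
#'
#' @param model A `gad_fcn`.
#' @param images Labeled cell-image tibble.
#' @return A list with `loss` and `accuracy`.
#' @export
fcn_evaluate <- function(model, images) {
  probs <- fcn_forward(model, images)
  y <- as.integer(images$label == "positive")
  w <- if ("sample_weight" %in% names(images)) images$sample_weight else rep(1, nrow(images))
  py <- pmax(ifelse(y == 1, probs[, "positive"], probs[, "negative"]), 1e-12)
  pred <- ifelse(probs[, "positive"] > probs[, "negative"], 1L, 0L)
  list(loss = sum(w * -log(py)) / sum(w), accuracy = mean(pred == y))
}

#' @export
print.gad_fcn <- function(x, ...) {
  cat(sprintf("<gad_fcn> %d-channel, features %s, %s, %d parameters\n",
              x$spec$n_channels, paste(x$spec$features, collapse = "/"),
              if (x$trained) sprintf("trained (checkpoint epoch %d)", x$checkpoint_epoch)
              else "untrained", n_parameters(x)))
  invisible(x)
}

#' Tidy a trained classifier: the per-epoch training history
#' @param x A trained `gad_fcn`.
#' @param ... Unused.
#' @return A tibble with one row per epoch.
#' @export
tidy.gad_fcn <- function(x, ...) {
  assert_that(x$trained, "model has no training history yet")
  x$history
}

#' One-row model summary
#' @param x A `gad_fcn`.
#' @param ... Unused.
#' @return A tibble: epochs, checkpoint epoch, best validation loss, size.
#' @export
glance.gad_fcn <- function(x, ...) {
  tibble::tibble(
    epochs = if (x$trained) nrow(x$history) else 0L,
    checkpoint_epoch = x$checkpoint_epoch,
    best_val_loss = if (x$trained) x$best_val_loss else NA_real_,
    n_parameters = n_parameters(x))
}

#' Training-history curves
#' @param object A trained `gad_fcn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gad_fcn <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "metric")
  long$set <- ifelse(grepl("^val_", long$metric), "validation", "training")
  long$what <- sub("^val_", "", long$metric)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$checkpoint_epoch, linetype = 2) +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL)
}

#' Save / load a trained model as a JSON checkpoint with manifest
#'
#' @param model A `gad_fcn`.
#' @param path Output file (JSON).
#' @return `write_fcn` returns `path` invisibly; `read_fcn` the model.
#' @export
write_fcn <- function(model, path) {
  payload <- list(
    manifest = list(spec = unclass(model$spec),
                    config = if (!is.null(model$config)) unclass(model$config),
                    seed = model$seed,
                    checkpoint_epoch = model$checkpoint_epoch,
                    trained = model$trained),
    params = model$params,
    history = model$history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fcn
#' @export
read_fcn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(fcn_spec, payload$manifest$spec[
    c("n_channels", "features", "kernel", "dropout", "inner_pool")])
  params <- payload$params
  params$conv_w <- lapply(params$conv_w, as.matrix)
  params$out_w <- as.matrix(params$out_w)
  params$kernel <- as.integer(params$kernel)
  params$inner_pool <- as.logical(params$inner_pool)
  model <- structure(list(spec = spec, params = params,
                          trained = isTRUE(payload$manifest$trained),
                          history = if (!is.null(payload$history))
                            tibble::as_tibble(payload$history),
                          checkpoint_epoch = payload$manifest$checkpoint_epoch,
                          seed = payload$manifest$seed),
                     class = "gad_fcn")
  model
}
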