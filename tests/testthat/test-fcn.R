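# fully convolutional classifier

test_that("initialization is seeded and size-agnostic in parameter count", {
  spec <- fcn_spec(2)
  a <- build_fcn(spec, seed = 11)
  b <- build_fcn(spec, seed = 11)
  expect_identical(a$params, b$params)
  c <- build_fcn(spec, seed = 12)
  expect_false(identical(a$params$conv_w[[1]], c$params$conv_w[[1]]))
  # no fully connected hidden layer: parameters do not grow with input size
  expect_equal(n_parameters(a),
               sum(vapply(a$params$conv_w, length, 1)) + 2 * sum(spec$features) +
                 2 * spec$features[3] + 2)
  expect_error(fcn_spec(4), "n_channels")
  expect_error(fcn_spec(2, features = c(8, 16)), "three convolutional blocks")
})

test_that("forward yields softmax probabilities for any input size", {
  model <- build_fcn(fcn_spec(2), seed = 5)
  imgs <- list(array(rnorm(32 * 32 * 2), c(32, 32, 2)),
               array(rnorm(57 * 41 * 2), c(57, 41, 2)),
               array(rnorm(9 * 70 * 2), c(9, 70, 2)))
  probs <- fcn_forward(model, imgs)
  expect_equal(dim(probs), c(3, 2))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-9)
  # duplicated sample in one batch gives identical outputs (eval mode)
  dup <- fcn_forward(model, list(imgs[[1]], imgs[[1]], imgs[[2]]))
  expect_equal(dup[1, ], dup[2, ], tolerance = 0)
  # channel mismatch is rejected
  expect_error(fcn_forward(model, list(array(0, c(10, 10, 3)))), "mismatch")
})

test_that("prediction ties break toward the negative class", {
  model <- build_fcn(fcn_spec(1), seed = 2)
  model$params$out_w[] <- 0  # forces logits (0, 0) -> probabilities (0.5, 0.5)
  model$params$out_b[] <- 0
  pred <- predict(model, list(array(rnorm(100), c(10, 10, 1))))
  expect_equal(pred$.pred_negative, 0.5)
  expect_equal(pred$.pred_class, "negative")
})

test_that("training learns a separable problem and checkpoints the best epoch", {
  tbl <- separable_crops(n_per_class = 45, seed = 42)
  train <- tbl[1:70, ]; test <- tbl[71:90, ]
  attr(train, "channels") <- "GAD67"; attr(test, "channels") <- "GAD67"
  fit <- train_fcn(train, test, config = train_config(epochs = 50, seed = 3))
  expect_gte(fcn_evaluate(fit, train)$accuracy, 0.95)
  h <- tidy(fit)
  expect_equal(fit$checkpoint_epoch, which.min(h$val_loss))
  # returned weights reproduce the minimum recorded validation loss
  expect_equal(fcn_evaluate(fit, test)$loss, min(h$val_loss), tolerance = 1e-8)
  expect_equal(fit$best_val_loss, min(h$val_loss), tolerance = 1e-12)
})

test_that("training is bit-reproducible under a fixed seed", {
  tbl <- separable_crops(n_per_class = 15, seed = 7)
  train <- tbl[1:24, ]; test <- tbl[25:30, ]
  attr(train, "channels") <- "GAD67"; attr(test, "channels") <- "GAD67"
  cfg <- train_config(epochs = 6, seed = 99)
  f1 <- train_fcn(train, test, config = cfg)
  f2 <- train_fcn(train, test, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("degenerate configurations error out", {
  tbl <- separable_crops(n_per_class = 10, seed = 1)
  expect_error(train_config(epochs = 0), "epochs")
  one_class <- tbl[tbl$label == "positive", ]
  attr(one_class, "channels") <- "GAD67"
  expect_error(train_fcn(one_class, tbl, config = train_config(epochs = 1)),
               "both classes")
})

test_that("SGD optimizer path runs and records history", {
  tbl <- separable_crops(n_per_class = 12, seed = 3)
  train <- tbl[1:18, ]; test <- tbl[19:24, ]
  attr(train, "channels") <- "GAD67"; attr(test, "channels") <- "GAD67"
  cfg <- train_config(optimizer = "sgd", epochs = 4, seed = 8)
  expect_equal(cfg$learning_rate, 1e-4)
  fit <- train_fcn(train, test, config = cfg)
  expect_equal(nrow(tidy(fit)), 4)
  expect_true(all(is.finite(tidy(fit)$val_loss)))
})

test_that("checkpoint files round-trip through JSON", {
  tbl <- separable_crops(n_per_class = 12, seed = 5)
  train <- tbl[1:18, ]; test <- tbl[19:24, ]
  attr(train, "channels") <- "GAD67"; attr(test, "channels") <- "GAD67"
  fit <- train_fcn(train, test, config = train_config(epochs = 3, seed = 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_fcn(fit, f)
  back <- read_fcn(f)
  expect_equal(back$checkpoint_epoch, fit$checkpoint_epoch)
  p1 <- fcn_forward(fit, test)
  p2 <- fcn_forward(back, test)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the classifier beats a label-permutation null on the joint signal", {
  ds <- small_dataset()
  crops <- ds$crops
  ch <- attr(crops, "channels")
  sel <- select_channels(crops, c("NeuN", "Nissl"))
  set.seed(15)
  ids <- unique(sel$cell_id)
  test_ids <- sample(ids, floor(0.25 * length(ids)))
  test <- sel[sel$cell_id %in% test_ids, ]
  train <- sel[!(sel$cell_id %in% test_ids), ]
  attr(test, "channels") <- c("NeuN", "Nissl")
  attr(train, "channels") <- c("NeuN", "Nissl")
  bal <- balance_downsample(train, seed = 16)
  fit <- train_fcn(bal$records, test,
                   config = train_config(epochs = 45, seed = 17),
                   spec = fcn_spec(2))
  pred <- predict(fit, test)$.pred_class
  obs <- evaluate_predictions(pred, test$label)$weighted_f1
  set.seed(18)
  null <- replicate(200, {
    evaluate_predictions(pred, sample(test$label))$weighted_f1
  })
  expect_gt(obs, mean(null) + 3 * sd(null))
})
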