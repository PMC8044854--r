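# Dataset assembly: class balancing with compensatory weights, cell-level
# fold plans, channel selection, zero-padded batches.

#' Downsample the majority class to a 1:1 ratio with compensatory weights
#'
#' The majority class is randomly downsampled (without replacement) to the
#' minority count; the retained majority records receive
#' `sample_weight = downsampling factor` (majority-before / majority-after)
#' so the weighted effective class counts equal the pre-balance counts and
#' model outputs stay interpretable as probabilities.
#'
#' @param records A tibble with a `label` column (`"positive"`/`"negative"`).
#' @param seed Integer seed for the subsample draw.
#' @return A list: `records` (balanced tibble with updated `sample_weight`),
#'   `class_weights` (named numeric), `downsampling_factor`.
#' @export
balance_downsample <- function(records, seed = 1) {
  counts <- table(factor(records$label, levels = CLASS_LEVELS))
  assert_that(all(counts > 0), "both classes must be present to balance")
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(CLASS_LEVELS, minority)
  n_min <- min(counts); n_maj <- max(counts)
  if (n_min == n_maj) {
    out <- records
    out$sample_weight <- 1
    return(list(records = out, class_weights = c(negative = 1, positive = 1),
                downsampling_factor = 1))
  }
  factor_ds <- as.numeric(n_maj) / as.numeric(n_min)
  set.seed(seed)
  maj_rows <- which(records$label == majority)
  keep_maj <- sort(sample(maj_rows, n_min))
  keep <- sort(c(which(records$label == minority), keep_maj))
  out <- records[keep, , drop = FALSE]
  out$sample_weight <- ifelse(out$label == majority, factor_ds, 1)
  cw <- setNames(c(1, 1), CLASS_LEVELS)
  cw[majority] <- factor_ds
  list(records = out, class_weights = cw, downsampling_factor = factor_ds)
}

#' Cell-level validation/fold assignment
#'
#' Holds out 20% of the *cells* (floor) as a validation set and partitions
#' the remaining cells into `n_folds` segments of as-equal-as-possible size.
#' Assignment is at cell level so that every crop of a physical cell shares
#' one fold (no leakage between planes of the same cell).
#'
#' @param cell_ids Vector of distinct cell ids (duplicates are collapsed).
#' @param seed Integer seed.
#' @param n_folds Number of cross-validation segments (default 5).
#' @param validation_fraction Hold-out fraction (default 0.2).
#' @return A tibble of class `fold_plan`: `cell_id`, `split`
#'   (`"validation"` or `"fold-1"` ... `"fold-k"`), with the seed as attribute.
#' @export
make_fold_plan <- function(cell_ids, seed = 1, n_folds = 5,
                           validation_fraction = 0.2) {
  ids <- unique(cell_ids)
  assert_that(length(ids) >= 2 * n_folds,
              "too few distinct cells to fill the folds")
  set.seed(seed)
  ids <- sample(ids)
  n_val <- floor(validation_fraction * length(ids))
  val <- ids[seq_len(n_val)]
  rest <- ids[-seq_len(n_val)]
  # folds as equal as integer division allows; the first (n %% k) folds get +1
  base <- length(rest) %/% n_folds
  extra <- length(rest) %% n_folds
  sizes <- rep(base, n_folds) + c(rep(1, extra), rep(0, n_folds - extra))
  fold <- rep(paste0("fold-", seq_len(n_folds)), times = sizes)
  plan <- tibble::tibble(
    cell_id = c(val, rest),
    split = c(rep("validation", n_val), fold))
  plan <- dplyr::arrange(plan, .data$cell_id)
  attr(plan, "seed") <- seed
  attr(plan, "n_folds") <- n_folds
  class(plan) <- c("fold_plan", class(plan))
  plan
}

#' All nonempty channel combinations
#'
#' The seven nonempty subsets of (GAD67, NeuN, Nissl), each in canonical
#' order, largest first.
#'
#' @return A list of character vectors.
#' @export
channel_combos <- function() {
  list(c("GAD67", "NeuN", "Nissl"),
       c("NeuN", "Nissl"),
       c("GAD67", "Nissl"),
       c("GAD67", "NeuN"),
       "GAD67", "NeuN", "Nissl")
}

#' Restrict cell images to a channel combination
#'
#' @param images Cell-image tibble with list-column `crop` and a `channels`
#'   attribute.
#' @param combo Character vector of channel names (any order; canonical
#'   GAD67, NeuN, Nissl order is enforced in the output).
#' @return The tibble with crops restricted to `combo`.
#' @export
select_channels <- function(images, combo) {
  have <- attr(images, "channels")
  assert_that(!is.null(have), "images must carry a 'channels' attribute")
  combo <- canonical_channels(combo, GAD_CHANNELS)
  missing <- setdiff(combo, have)
  assert_that(length(missing) == 0,
              paste0("channel(s) not present: ", paste(missing, collapse = ", ")))
  idx <- match(combo, have)
  out <- images
  out$crop <- lapply(images$crop, function(a) a[, , idx, drop = FALSE])
  attr(out, "channels") <- combo
  out
}

#' Assemble zero-padded batches
#'
#' Shuffles the records (seeded), then groups them into batches of
#' `batch_size`; within each batch every crop is zero-padded at the bottom
#' and right to the largest height and width in that batch. The final partial
#' batch is kept. Per-sample labels and weights travel with each batch.
#'
#' @param images Cell-image tibble (`crop` list-column, optional `label`,
#'   `sample_weight`).
#' @param batch_size Batch size (default 8).
#' @param seed Seed for the shuffle (ignored when `shuffle = FALSE`).
#' @param shuffle Shuffle before batching (disable for evaluation).
#' @return A list of batches, each `list(x = array(h, w, ch, n), y, w, rows)`;
#'   `y` is 0/1 (negative/positive), `rows` the original row indices.
#' @export
make_batches <- function(images, batch_size = 8, seed = 1, shuffle = TRUE) {
  n <- nrow(images)
  assert_that(n > 0, "no images to batch")
  ord <- seq_len(n)
  if (shuffle) {
    set.seed(seed)
    ord <- sample(ord)
  }
  starts <- seq(1, n, by = batch_size)
  lapply(starts, function(s) {
    rows <- ord[s:min(s + batch_size - 1, n)]
    crops <- images$crop[rows]
    hs <- vapply(crops, function(a) dim(a)[1], numeric(1))
    ws <- vapply(crops, function(a) dim(a)[2], numeric(1))
    nc <- dim(crops[[1]])[3]
    H <- max(hs); W <- max(ws)
    x <- array(0, dim = c(H, W, nc, length(rows)))
    for (i in seq_along(rows)) {
      x[seq_len(hs[i]), seq_len(ws[i]), , i] <- crops[[i]]
    }
    y <- if ("label" %in% names(images)) {
      as.integer(images$label[rows] == "positive")
    } else rep(NA_integer_, length(rows))
    w <- if ("sample_weight" %in% names(images)) {
      images$sample_weight[rows]
    } else rep(1, length(rows))
    list(x = x, y = y, w = w, rows = rows)
  })
}

# strip the padding from a batch, recovering the original crops
unbatch <- function(batch, heights, widths) {
  lapply(seq_along(heights), function(i) {
    batch$x[seq_len(heights[i]), seq_len(widths[i]), , i, drop = FALSE]
  })
}
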