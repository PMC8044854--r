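# dataset assembly: balancing, fold plans, channel selection, batches

fake_records <- function(n_pos, n_neg) {
  tibble::tibble(
    cell_id = seq_len(n_pos + n_neg),
    label = c(rep("positive", n_pos), rep("negative", n_neg)),
    value = rnorm(n_pos + n_neg),
    sample_weight = 1)
}

test_that("downsampling reaches 1:1 and compensates with weights", {
  rec <- fake_records(30, 90)
  bal <- balance_downsample(rec, seed = 4)
  tab <- table(bal$records$label)
  expect_equal(unname(tab["positive"]), 30)
  expect_equal(unname(tab["negative"]), 30)
  expect_equal(bal$downsampling_factor, 3)
  expect_equal(unname(bal$class_weights["negative"]), 3)
  expect_equal(unname(bal$class_weights["positive"]), 1)
  # weighted effective counts equal the pre-balance counts
  eff <- tapply(bal$records$sample_weight, bal$records$label, sum)
  expect_equal(unname(eff["positive"]), 30)
  expect_equal(unname(eff["negative"]), 90)
  # sampling only: retained rows are original rows, values untouched
  expect_true(all(bal$records$value %in% rec$value))
})

test_that("already balanced data passes through with unit weights", {
  rec <- fake_records(40, 40)
  bal <- balance_downsample(rec, seed = 1)
  expect_equal(nrow(bal$records), 80)
  expect_true(all(bal$records$sample_weight == 1))
  expect_equal(bal$downsampling_factor, 1)
})

test_that("balancing requires both classes", {
  expect_error(balance_downsample(fake_records(10, 0)), "both classes")
})

test_that("fold plan: 100 cells -> 20 validation and five folds of 16", {
  plan <- make_fold_plan(1:100, seed = 3)
  expect_equal(sum(plan$split == "validation"), 20)
  for (f in 1:5) expect_equal(sum(plan$split == paste0("fold-", f)), 16)
  # partition: all cells exactly once
  expect_setequal(plan$cell_id, 1:100)
  expect_equal(nrow(plan), 100)
  # determinism
  expect_equal(as.data.frame(make_fold_plan(1:100, seed = 3)),
               as.data.frame(plan))
  # a different seed actually reshuffles
  plan2 <- make_fold_plan(1:100, seed = 4)
  expect_false(identical(plan$split, plan2$split))
  expect_error(make_fold_plan(1:7, seed = 1), "too few")
})

test_that("fold plan handles non-divisible cell counts", {
  plan <- make_fold_plan(1:103, seed = 2)
  expect_equal(sum(plan$split == "validation"), 20)  # floor(0.2 * 103)
  sizes <- table(plan$split[plan$split != "validation"])
  expect_equal(sort(unname(as.integer(sizes))), c(16, 16, 17, 17, 17))
})

test_that("channel selection subsets in canonical order", {
  crops <- lapply(1:3, function(i) array(seq_len(4 * 4 * 3), c(4, 4, 3)))
  tbl <- with_channels(tibble::tibble(crop = crops), c("GAD67", "NeuN", "Nissl"))
  two <- select_channels(tbl, c("Nissl", "NeuN"))
  expect_equal(attr(two, "channels"), c("NeuN", "Nissl"))
  expect_equal(dim(two$crop[[1]]), c(4, 4, 2))
  expect_equal(two$crop[[1]][, , 1], tbl$crop[[1]][, , 2])
  expect_equal(select_channels(tbl, c("GAD67", "NeuN", "Nissl"))$crop, tbl$crop)
  one <- select_channels(tbl, "GAD67")
  expect_equal(dim(one$crop[[1]])[3], 1)
  only2 <- select_channels(tbl, c("NeuN", "Nissl"))
  expect_error(select_channels(only2, "GAD67"), "not present")
})

test_that("there are exactly seven channel combinations", {
  combos <- channel_combos()
  expect_equal(length(combos), 7)
  expect_equal(anyDuplicated(vapply(combos, paste, "", collapse = "+")), 0)
})

test_that("batches pad bottom/right to the in-batch maximum", {
  set.seed(9)
  crops <- list(array(1, c(40, 48, 2)), array(2, c(30, 20, 2)),
                array(3, c(10, 48, 2)))
  crops <- c(crops, lapply(4:8, function(i) array(i, c(20, 20, 2))))
  tbl <- with_channels(tibble::tibble(crop = crops,
                                      label = rep(c("positive", "negative"), 4),
                                      sample_weight = 1), c("NeuN", "Nissl"))
  b <- make_batches(tbl, batch_size = 8, shuffle = FALSE)
  expect_equal(length(b), 1)
  expect_equal(dim(b[[1]]$x), c(40, 48, 2, 8))
  # content anchored top-left, zeros outside each crop's extent
  expect_equal(b[[1]]$x[1:30, 1:20, , 2], crops[[2]])
  expect_true(all(b[[1]]$x[31:40, , , 2] == 0))
  expect_true(all(b[[1]]$x[, 21:48, , 2] == 0))
  # stripping the padding recovers each crop exactly
  rec <- gadcell:::unbatch(b[[1]], vapply(crops, function(a) dim(a)[1], 1),
                           vapply(crops, function(a) dim(a)[2], 1))
  for (i in seq_along(crops)) {
    expect_equal(array(rec[[i]], dim(crops[[i]])), crops[[i]])
  }
})

test_that("17 crops become batches of 8, 8 and 1; same sizes need no padding", {
  crops <- lapply(1:17, function(i) array(i, c(12, 12, 1)))
  tbl <- with_channels(tibble::tibble(crop = crops), "GAD67")
  b <- make_batches(tbl, batch_size = 8, seed = 5)
  expect_equal(vapply(b, function(x) dim(x$x)[4], 1), c(8, 8, 1))
  expect_equal(dim(b[[1]]$x)[1:2], c(12, 12))  # no padding added
  # seeded shuffle is deterministic
  b2 <- make_batches(tbl, batch_size = 8, seed = 5)
  expect_identical(lapply(b, `[[`, "rows"), lapply(b2, `[[`, "rows"))
})
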