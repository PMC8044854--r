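# synthetic micrograph generator

test_that("config invariants are enforced", {
  expect_error(synth_config(positive_fraction = 0), "positive_fraction")
  expect_error(synth_config(positive_fraction = 1), "positive_fraction")
  expect_error(synth_config(n_cells = 1), "n_cells")
  expect_error(synth_config(n_planes = 0), "n_planes")
})

test_that("generation is seed-deterministic down to the pixel and the file", {
  cfg <- synth_config(n_cells = 20, image_size = c(224, 224), n_planes = 3,
                      seed = 33)
  a <- generate_micrograph(cfg)
  b <- generate_micrograph(cfg)
  expect_identical(a$stack$intensities, b$stack$intensities)
  expect_identical(a$truth$cells, b$truth$cells)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(a, d1); write_fixture(b, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in setdiff(f1, "config.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("positive count stays within the binomial range (seed 7, n = 200)", {
  cfg <- synth_config(n_cells = 200, positive_fraction = 0.15,
                      image_size = c(800, 800), n_planes = 1, seed = 7)
  sim <- generate_micrograph(cfg)
  n_pos <- sum(sim$truth$cells$label == "positive")
  # central 99.9% range of Binomial(200, 0.15)
  expect_gte(n_pos, 15)
  expect_lte(n_pos, 45)
})

test_that("without touching pairs every cell is its own connected component", {
  cfg <- synth_config(n_cells = 40, touching_pair_fraction = 0,
                      image_size = c(400, 400), n_planes = 1, seed = 5)
  sim <- generate_micrograph(cfg)
  expect_equal(max(sim$truth$label_mask), 40)
  expect_equal(length(unique(sim$truth$cells$component_label)), 40)
})

test_that("fused pairs share one label and the mask label count matches", {
  cfg <- synth_config(n_cells = 40, touching_pair_fraction = 0.5,
                      image_size = c(480, 480), n_planes = 1, seed = 8)
  sim <- generate_micrograph(cfg)
  cells <- sim$truth$cells
  n_pairs <- length(unique(stats::na.omit(cells$pair_id)))
  expect_equal(n_pairs, 10)
  # connected placements = cells - one per fused pair
  expect_equal(max(sim$truth$label_mask), 40 - n_pairs)
  for (p in unique(stats::na.omit(cells$pair_id))) {
    labs <- cells$component_label[which(cells$pair_id == p)]
    expect_equal(labs[1], labs[2])
  }
})

test_that("zero joint signal makes channels 2-3 class-indistinguishable", {
  cfg <- synth_config(n_cells = 100, joint_signal_strength = 0,
                      image_size = c(520, 520), n_planes = 1,
                      positive_fraction = 0.5, touching_pair_fraction = 0)
  # pool four micrographs for ~300 analyzed cells
  ds0 <- build_synthetic_dataset(n_stacks = 4, config = cfg, seed = 22,
                                 drop_unknown = TRUE)
  st <- ds0$stats[ds0$stats$label %in% c("positive", "negative"), ]
  expect_gte(nrow(st), 280)
  for (ch in c("NeuN", "Nissl")) {
    p <- stats::t.test(st[[paste0("mean_", ch)]] ~ st$label)$p.value
    expect_gt(p, 0.01, label = paste("two-sample test,", ch))
  }
})

test_that("channels 2-3 marginals overlap between classes at defaults", {
  ds <- small_dataset()
  st <- ds$stats[ds$stats$label %in% c("positive", "negative"), ]
  for (ch in c("NeuN", "Nissl")) {
    x <- st[[paste0("mean_", ch)]][st$label == "positive"]
    y <- st[[paste0("mean_", ch)]][st$label == "negative"]
    # histogram overlap coefficient on a common coarse grid (the positive
    # class is small, so fine bins would understate the overlap)
    br <- seq(min(c(x, y)), max(c(x, y)), length.out = 9)
    hx <- hist(x, breaks = br, plot = FALSE)$counts / length(x)
    hy <- hist(y, breaks = br, plot = FALSE)$counts / length(y)
    ovl <- sum(pmin(hx, hy))
    expect_gt(ovl, 0.5, label = paste("overlap coefficient,", ch))
  }
})

test_that("area and circularity do not differ by class", {
  ds <- small_dataset()
  st <- ds$stats[ds$stats$label %in% c("positive", "negative"), ]
  expect_gt(stats::t.test(st$area ~ st$label)$p.value, 0.01)
  expect_gt(stats::t.test(st$circularity ~ st$label)$p.value, 0.01)
})

test_that("fixture round-trips exactly and annotations are complete", {
  cfg <- synth_config(n_cells = 12, image_size = c(128, 128), n_planes = 2,
                      seed = 9)
  sim <- generate_micrograph(cfg)
  d <- withr::local_tempdir()
  paths <- write_fixture(sim, d)
  expect_true(all(file.exists(paths)))
  back <- read_fixture(d)
  expect_equal(back$stack$intensities, sim$stack$intensities,
               ignore_attr = FALSE)
  expect_identical(back$label_mask, sim$truth$label_mask)
  expect_equal(nrow(back$annotations), nrow(sim$truth$cells))
  expect_equal(max(back$label_mask), max(sim$truth$label_mask))
})

test_that("overcrowded configurations are rejected", {
  cfg <- synth_config(n_cells = 200, image_size = c(100, 100), n_planes = 1,
                      seed = 1)
  expect_error(generate_micrograph(cfg), "overcrowd")
})
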