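# preprocessing: planes, normalization, segmentation, splitting, stats, crops

make_stack <- function(H = 40, W = 40, planes = 10, seed = 1) {
  set.seed(seed)
  arr <- array(runif(H * W * planes * 3, 0, 1000), c(H, W, planes, 3))
  gadcell:::new_gad_stack(arr, c("GAD67", "NeuN", "Nissl"))
}

test_that("plane extraction defaults to first and last, collapses duplicates", {
  st <- make_stack(planes = 10)
  pl <- extract_planes(st)
  expect_setequal(unique(pl$plane), c(1, 10))
  expect_equal(pl$channel[pl$plane == 1], c("GAD67", "NeuN", "Nissl"))
  st1 <- make_stack(planes = 1)
  pl1 <- extract_planes(st1)
  expect_equal(unique(pl1$plane), 1)
  expect_equal(nrow(pl1), 3)
  pl3 <- extract_planes(st, preprocess_config(planes_used = 3))
  expect_equal(unique(pl3$plane), 3)
  expect_error(extract_planes(st, preprocess_config(planes_used = 11)),
               "out of range")
})

test_that("normalization maps mean +/- SD to [0, 1] without clipping", {
  set.seed(2)
  plane <- matrix(rnorm(900, 100, 20), 30, 30)
  # exact mean 100, sd 20 by affine correction
  plane <- (plane - mean(plane)) / sd(plane) * 20 + 100
  nz <- normalize_plane(plane)
  expect_equal(mean(nz), 0.5, tolerance = 1e-12)
  idx <- which.max(plane)  # check the affine map pointwise
  expect_equal(nz[idx], (plane[idx] - 80) / 40, tolerance = 1e-12)
  plane[1, 1] <- 60  # recompute expected under new stats
  m <- mean(plane); s <- sd(plane)
  expect_equal(normalize_plane(plane)[1, 1], (60 - (m - s)) / (2 * s))
})

test_that("normalization is invariant under positive affine rescaling", {
  set.seed(3)
  for (i in 1:5) {
    plane <- matrix(runif(400, 0, 5000), 20, 20)
    a <- runif(1, 0.1, 10); b <- runif(1, -100, 100)
    expect_equal(normalize_plane(a * plane + b), normalize_plane(plane),
                 tolerance = 1e-8)
  }
})

test_that("constant plane normalizes to all 0.5 with a warning", {
  expect_warning(out <- normalize_plane(matrix(7, 5, 5)), "constant")
  expect_true(all(out == 0.5))
})

test_that("external masks pass through with consecutive relabeling", {
  plane <- matrix(0, 20, 20)
  m <- matrix(0L, 20, 20)
  m[2:4, 2:4] <- 1L; m[10:13, 10:13] <- 1L; m[16:18, 3:5] <- 1L
  sm <- segment_cells(plane, external_mask = m)
  expect_setequal(unique(sm$labels[sm$labels > 0]), 1:3)
  expect_equal(sm$source, "external-mask")
  # labeled mask with gaps relabels consecutively but keeps regions
  m2 <- m; m2[m2 > 0] <- 0L; m2[2:4, 2:4] <- 5L; m2[10:13, 10:13] <- 9L
  sm2 <- segment_cells(plane, external_mask = m2)
  expect_setequal(unique(sm2$labels[sm2$labels > 0]), 1:2)
  expect_error(segment_cells(plane, external_mask = matrix(0L, 5, 5)), "shape")
})

test_that("fallback segmentation finds bright blobs and tolerates empty planes", {
  set.seed(4)
  plane <- matrix(rnorm(120 * 120, 100, 10), 120, 120)
  centers <- cbind(c(20, 20, 60, 100, 90), c(20, 90, 55, 30, 100))
  for (k in 1:5) {
    for (r in -8:8) for (c in -8:8) {
      if (r^2 + c^2 <= 64) {
        plane[centers[k, 1] + r, centers[k, 2] + c] <- 4000 + rnorm(1, 0, 50)
      }
    }
  }
  sm <- segment_cells(plane)
  expect_equal(max(sm$labels), 5)
  expect_equal(sm$source, "internal-fallback")
  # a constant background plane yields zero labels and an empty ROI list
  flat <- matrix(100, 20, 20)
  sm0 <- segment_cells(flat)
  expect_equal(max(sm0$labels), 0)
  expect_equal(nrow(split_rois_erosion_dilation(sm0)), 0)
})

test_that("a convex disc passes through the splitter unchanged", {
  m <- disc_mask(10)
  lab <- matrix(0L, nrow(m), ncol(m)); lab[m] <- 1L
  rois <- split_rois_erosion_dilation(lab)
  expect_equal(nrow(rois), 1)
  expect_true(is.na(rois$split_lineage[1]))
  expect_equal(rois$area[1], sum(m))
  # identical pixel set
  rec <- matrix(FALSE, nrow(m), ncol(m))
  rec[(rois$bb_r[1] + 1):(rois$bb_r[1] + rois$bb_h[1]),
      (rois$bb_c[1] + 1):(rois$bb_c[1] + rois$bb_w[1])][rois$patch[[1]]] <- TRUE
  expect_identical(rec, m)
})

test_that("a dumbbell splits into two disjoint children inside the parent", {
  size <- 60
  m <- matrix(FALSE, size, size)
  for (r in 1:size) for (c in 1:size) {
    if ((r - 30)^2 + (c - 23)^2 <= 100 || (r - 30)^2 + (c - 37)^2 <= 100) {
      m[r, c] <- TRUE
    }
  }
  lab <- matrix(0L, size, size); lab[m] <- 1L
  rois <- split_rois_erosion_dilation(lab)
  expect_equal(nrow(rois), oracle_split_count(m))
  expect_equal(nrow(rois), 2)
  expect_true(all(rois$split_lineage == 1))
  masks <- lapply(seq_len(nrow(rois)), function(i) {
    rec <- matrix(FALSE, size, size)
    rec[(rois$bb_r[i] + 1):(rois$bb_r[i] + rois$bb_h[i]),
        (rois$bb_c[i] + 1):(rois$bb_c[i] + rois$bb_w[i])][rois$patch[[i]]] <- TRUE
    rec
  })
  expect_false(any(masks[[1]] & masks[[2]]))       # disjoint
  expect_true(all((masks[[1]] | masks[[2]]) <= m)) # union within parent
})

test_that("split counts match the brute-force erosion-scan oracle", {
  cases <- 0
  for (s in 1:40) {
    m <- random_blob_mask(64, n_blobs = sample(2:5, 1), seed = 700 + s)
    lab <- gadcell:::label_components(m > 0)
    rois <- split_rois_erosion_dilation(lab)
    for (L in seq_len(max(lab))) {
      got <- sum(rois$parent_label == L)
      want <- oracle_split_count(lab == L)
      expect_equal(got, want, label = sprintf("mask %d label %d", s, L))
      cases <- cases + 1
    }
  }
  expect_gte(cases, 100)
})

test_that("area filter keeps the boundary value and preserves order", {
  rois <- tibble::tibble(roi_id = 1:4, area = c(100, 179, 180, 500))
  kept <- filter_rois_by_area(rois, min_area = 180)
  expect_equal(kept$area, c(180, 500))
  expect_equal(filter_rois_by_area(rois[0, ], min_area = 180)$roi_id, integer(0))
  expect_equal(filter_rois_by_area(rois, min_area = 1), rois)
  # monotonicity: raising the threshold never increases the survivor count
  n_kept <- vapply(c(1, 100, 180, 300, 600), function(thr) {
    nrow(filter_rois_by_area(rois, min_area = thr))
  }, numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("ROI statistics: constant region mean, square area, disc circularity", {
  H <- 60; arr <- array(50, c(H, H, 1, 3))
  st <- gadcell:::new_gad_stack(arr, c("GAD67", "NeuN", "Nissl"))
  m <- disc_mask(20, size = H, center = c(30, 30))
  lab <- matrix(0L, H, H); lab[m] <- 1L
  rois <- split_rois_erosion_dilation(lab, preprocess_config(max_erosion_iters = 2))
  stats <- compute_roi_stats(rois, st)
  expect_equal(stats$mean_GAD67, 50)
  expect_equal(stats$mean_Nissl, 50)
  expect_gte(stats$circularity, 0.85)
  expect_lte(stats$circularity, 1.05)
  sq <- matrix(0L, 20, 20); sq[6:15, 6:15] <- 1L
  rsq <- split_rois_erosion_dilation(sq, preprocess_config(max_erosion_iters = 2))
  expect_equal(rsq$area, 100)
})

test_that("crops are tight unmasked rectangles from normalized planes", {
  st <- make_stack(H = 50, W = 60, planes = 2, seed = 6)
  cfgp <- preprocess_config(planes_used = 1)
  planes <- extract_planes(st, cfgp)
  norm <- planes; norm$image <- lapply(planes$image, normalize_plane)
  patch <- matrix(TRUE, 20, 30)
  rois <- tibble::tibble(roi_id = 1L, parent_label = 1L, plane = 1L,
                         split_lineage = NA_integer_, area = 600L,
                         perimeter = 96, circularity = 4 * pi * 600 / 96^2,
                         bb_r = 5L, bb_c = 8L, bb_h = 20L, bb_w = 30L,
                         patch = list(patch))
  crops <- crop_cell_images(rois, norm, channels = c("GAD67", "NeuN"))
  expect_equal(dim(crops$crop[[1]]), c(20, 30, 2))
  # values at ROI-interior coordinates equal the normalized plane values
  nn <- norm$image[[which(norm$channel == "NeuN" & norm$plane == 1)]]
  expect_equal(crops$crop[[1]][3, 4, 2], nn[5 + 3, 8 + 4])
  expect_equal(attr(crops, "channels"), c("GAD67", "NeuN"))
})

test_that("pipeline links planes to shared cell ids and never alters pixels", {
  cfg <- synth_config(n_cells = 25, image_size = c(300, 300), seed = 13)
  sim <- generate_micrograph(cfg)
  before <- sim$stack$intensities
  pp <- preprocess_micrograph(sim$stack, masks = sim$truth$label_mask,
                              truth = sim$truth)
  expect_identical(sim$stack$intensities, before)
  # both selected planes of one physical cell share a cell id
  per_cell <- table(pp$crops$cell_id)
  expect_gt(mean(per_cell == 2), 0.8)
  two_plane <- names(per_cell)[per_cell == 2][1]
  rows <- pp$crops[pp$crops$cell_id == as.integer(two_plane), ]
  expect_setequal(rows$plane, c(1, 10))
  expect_equal(length(unique(rows$label)), 1)
})
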