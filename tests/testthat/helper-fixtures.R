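# shared fixture builders (all generated in code, seeded)

`%||%` <- function(a, b) if (is.null(a)) b else a

# attach the channels attribute a cell-image tibble needs
with_channels <- function(tbl, channels) {
  attr(tbl, "channels") <- channels
  tbl
}

# tiny linearly separable single-channel crops: bright vs dim
separable_crops <- function(n_per_class = 40, seed = 42, mu = c(0.3, 0.7)) {
  set.seed(seed)
  mk <- function(n, m) lapply(seq_len(n), function(i) {
    h <- sample(14:26, 1); w <- sample(14:26, 1)
    array(rnorm(h * w, m, 0.15), dim = c(h, w, 1))
  })
  tbl <- tibble::tibble(
    crop = c(mk(n_per_class, mu[1]), mk(n_per_class, mu[2])),
    label = rep(c("negative", "positive"), each = n_per_class),
    cell_id = seq_len(2 * n_per_class),
    sample_weight = 1)
  with_channels(tbl[sample(nrow(tbl)), ], "GAD67")
}

# rasterized disc as a logical matrix
disc_mask <- function(radius, size = 2 * radius + 11, center = NULL) {
  center <- center %||% c((size + 1) / 2, (size + 1) / 2)
  m <- matrix(FALSE, size, size)
  for (r in seq_len(size)) for (c in seq_len(size)) {
    if ((r - center[1])^2 + (c - center[2])^2 <= radius^2) m[r, c] <- TRUE
  }
  m
}

# random multi-blob binary mask (may contain fused blobs / border contact)
random_blob_mask <- function(size = 64, n_blobs = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(0, size, size)
  for (b in seq_len(n_blobs)) {
    r <- sample(seq_len(size), 1); c <- sample(seq_len(size), 1)
    rad <- sample(3:9, 1)
    rows <- pmax(1, r - rad):pmin(size, r + rad)
    cols <- pmax(1, c - rad):pmin(size, c + rad)
    for (i in rows) for (j in cols) {
      if ((i - r)^2 + (j - c)^2 <= rad^2) m[i, j] <- 1
    }
  }
  m
}

# independent brute-force oracle for the erosion-dilation split count:
# a single box erosion of size 2k+1 equals k iterated unit erosions, and the
# split count is the component count at the first k that disconnects the region
oracle_split_count <- function(region, max_iters = 10) {
  for (k in seq_len(max_iters)) {
    er <- EBImage::erode(EBImage::Image(region * 1),
                         EBImage::makeBrush(2L * k + 1L, "diamond"))
    m <- matrix(as.numeric(er), nrow(region), ncol(region)) > 0
    if (!any(m)) return(1L)
    nc <- max(gadcell:::label_components(m))
    if (nc > 1) return(nc)
  }
  1L
}

# brute-force confusion tally by explicit looping (oracle for the metrics)
oracle_confusion <- function(pred, truth, positive) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == positive && truth[i] == positive) tp <- tp + 1L
    else if (pred[i] == positive && truth[i] != positive) fp <- fp + 1L
    else if (pred[i] != positive && truth[i] != positive) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

oracle_prf <- function(cc) {
  prec <- if (cc$TP + cc$FP == 0) 0 else cc$TP / (cc$TP + cc$FP)
  rec <- if (cc$TP + cc$FN == 0) 0 else cc$TP / (cc$TP + cc$FN)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

# small cached synthetic dataset shared across test files
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_synthetic_dataset(
        n_stacks = 2, config = synth_config(n_cells = 80), seed = 101)
    }
    cache
  }
})
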