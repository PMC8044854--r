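# Synthetic multichannel micrograph generator -------------------------------
#
# Emulates the statistical regime of two-class (GAD67-positive vs -negative)
# neuron populations in confocal z-stacks:
#   * channel 1 (GAD67 analog): class-dependent mean fluorescence, separated
#     but overlapping between classes;
#   * channels 2-3 (NeuN / Nissl analogs): per-class marginal intensity
#     distributions are identical, but the *joint* pixel pattern carries the
#     class: the within-cell textures of the two channels are positively
#     correlated for one class and anticorrelated for the other;
#   * a configurable fraction of cells is placed as touching (fused) pairs;
#   * per-plane multiplicative gain drift plus additive background noise.

#' Configuration for the synthetic micrograph generator
#'
#' @param image_size Integer vector `(height, width)` in pixels.
#' @param n_cells Number of cells to place.
#' @param positive_fraction Probability that a cell is GAD67-positive.
#'   Interneurons are a minority in neocortex, hence the imbalanced default.
#' @param channel_models Named list (one entry per channel) of per-class
#'   within-cell mean-intensity models, each `list(positive = c(mean, sd),
#'   negative = c(mean, sd))` in arbitrary 16-bit fluorescence units.
#' @param joint_signal_strength Scalar in `[0, 1]`-ish range scaling how much
#'   class identity is encoded in the joint NeuN/Nissl texture correlation.
#'   At 0 the two classes are indistinguishable from channels 2-3.
#' @param touching_pair_fraction Fraction of cells placed as fused pairs.
#' @param cell_area_mean,cell_area_sd Mean/SD of ellipse area in px^2.
#' @param noise_sd Additive Gaussian background noise SD.
#' @param plane_drift Length-2 range of the per-plane multiplicative gain.
#' @param n_planes Number of z-planes (10 mirrors a typical confocal stack).
#' @param seed Integer seed; the whole micrograph is reproducible from it.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(image_size = c(512, 512),
                         n_cells = 100,
                         positive_fraction = 0.15,
                         channel_models = default_channel_models(),
                         joint_signal_strength = 1,
                         touching_pair_fraction = 0.1,
                         cell_area_mean = 340,
                         cell_area_sd = 70,
                         noise_sd = 400,
                         plane_drift = c(0.9, 1.1),
                         n_planes = 10,
                         seed = 1) {
  assert_that(length(image_size) == 2 && all(image_size >= 32),
              "image_size must be (height, width), each >= 32")
  assert_that(n_cells >= 2, "n_cells must be >= 2")
  assert_that(positive_fraction > 0 && positive_fraction < 1,
              "positive_fraction must lie strictly in (0, 1)")
  assert_that(n_planes >= 1, "n_planes must be >= 1")
  assert_that(touching_pair_fraction >= 0 && touching_pair_fraction <= 1,
              "touching_pair_fraction must lie in [0, 1]")
  assert_that(joint_signal_strength >= 0, "joint_signal_strength must be >= 0")
  assert_that(all(sort(names(channel_models)) == sort(GAD_CHANNELS)),
              "channel_models must have entries GAD67, NeuN, Nissl")
  structure(
    list(image_size = as.integer(image_size), n_cells = as.integer(n_cells),
         positive_fraction = positive_fraction, channel_models = channel_models,
         joint_signal_strength = joint_signal_strength,
         touching_pair_fraction = touching_pair_fraction,
         cell_area_mean = cell_area_mean, cell_area_sd = cell_area_sd,
         noise_sd = noise_sd, plane_drift = plane_drift,
         n_planes = as.integer(n_planes), seed = as.integer(seed)),
    class = "synth_config")
}

#' Default per-channel, per-class intensity models
#'
#' GAD67 means are separated by about 3.4 within-class SDs (overlapping but
#' informative); NeuN and Nissl have identical marginals for both classes, so
#' only their joint texture carries class information.
#'
#' @return Named list used as `channel_models` in [synth_config()].
#' @export
default_channel_models <- function() {
  list(
    GAD67 = list(positive = c(mean = 11000, sd = 1800),
                 negative = c(mean = 4800, sd = 1800)),
    NeuN  = list(positive = c(mean = 9000, sd = 1500),
                 negative = c(mean = 9000, sd = 1500)),
    Nissl = list(positive = c(mean = 9000, sd = 1500),
                 negative = c(mean = 9000, sd = 1500))
  )
}

# internal constants of the texture model
SYNTH_TEXTURE_SD <- 2000   # within-cell pixel texture amplitude
SYNTH_RHO_MEAN <- 0.5     # |mean| texture correlation at joint_signal_strength = 1
SYNTH_RHO_SD <- 0.35       # cell-to-cell spread of the correlation
SYNTH_BACKGROUND <- 800    # background fluorescence level

#' Generate a synthetic multichannel z-stack micrograph with ground truth
#'
#' Places elliptical cells (optionally as fused touching pairs), paints
#' class-dependent fluorescence into three channels over `n_planes` z-planes
#' with per-plane gain drift and additive noise, and returns the stack
#' together with per-cell ground truth and an annotation table.
#'
#' @param config A [synth_config()].
#' @return A list of class `gad_micrograph` with elements
#'   `stack` (a `gad_stack`: `intensities` array `h x w x planes x channels`,
#'   `channel_names`, `plane_stats` tibble), `truth` (per-cell tibble `cells`,
#'   `instance_mask` with one id per cell, `label_mask` with one id per
#'   connected component -- fused pairs share a label), and `annotations`
#'   (tibble: `cell_id`, `label`, `centroid_x`, `centroid_y`, `area_px2`).
#' @export
generate_micrograph <- function(config = synth_config()) {
  cfg <- config
  assert_that(inherits(cfg, "synth_config"), "config must be a synth_config")
  set.seed(cfg$seed)
  H <- cfg$image_size[1]; W <- cfg$image_size[2]

  n <- cfg$n_cells
  n_pairs <- floor(cfg$touching_pair_fraction * n / 2)
  labels <- ifelse(rbinom(n, 1, cfg$positive_fraction) == 1,
                   "positive", "negative")

  # ellipse geometry; same distribution for both classes
  areas <- pmax(60, rnorm(n, cfg$cell_area_mean, cfg$cell_area_sd))
  aspect <- runif(n, 1.0, 1.8)
  semi_a <- sqrt(areas * aspect / pi)
  semi_b <- sqrt(areas / (aspect * pi))
  angle <- runif(n, 0, pi)

  # --- placement ------------------------------------------------------------
  margin <- 4
  max_tries <- 60L * n
  placed_x <- numeric(n); placed_y <- numeric(n)
  pair_id <- rep(NA_integer_, n)
  rad <- semi_a  # conservative radius for spacing
  tries <- 0L
  ok_position <- function(x, y, r, upto) {
    if (upto == 0) return(TRUE)
    dx <- placed_x[seq_len(upto)] - x
    dy <- placed_y[seq_len(upto)] - y
    all(sqrt(dx^2 + dy^2) >= r + rad[seq_len(upto)] + 3)
  }
  i <- 1L
  pair_count <- 0L
  while (i <= n) {
    as_pair <- pair_count < n_pairs && i < n
    success <- FALSE
    while (tries < max_tries && !success) {
      tries <- tries + 1L
      x <- runif(1, margin + rad[i], W - margin - rad[i])
      y <- runif(1, margin + rad[i], H - margin - rad[i])
      if (as_pair) {
        j <- i + 1L
        theta <- runif(1, 0, 2 * pi)
        # fused pair: both ellipses aligned with the pair axis, overlapping waist
        d <- 0.85 * (semi_a[i] + semi_a[j])
        xj <- x + d * cos(theta); yj <- y + d * sin(theta)
        if (xj < margin + rad[j] || xj > W - margin - rad[j] ||
            yj < margin + rad[j] || yj > H - margin - rad[j]) next
        if (!ok_position(x, y, rad[i] + rad[j] + d, i - 1L)) next
        placed_x[i] <- x; placed_y[i] <- y
        placed_x[j] <- xj; placed_y[j] <- yj
        angle[i] <- theta; angle[j] <- theta
        pair_count <- pair_count + 1L
        pair_id[c(i, j)] <- pair_count
        success <- TRUE
        i <- i + 2L
      } else {
        if (!ok_position(x, y, rad[i], i - 1L)) next
        placed_x[i] <- x; placed_y[i] <- y
        success <- TRUE
        i <- i + 1L
      }
    }
    if (!success) {
      abort(paste0("could not place ", n, " cells in a ", H, "x", W,
                   " image within the retry budget (overcrowded configuration)"))
    }
  }

  # --- rasterize instance mask ------------------------------------------------
  instance <- matrix(0L, H, W)
  rr_norm <- matrix(Inf, H, W)  # elliptical radius of the owning cell
  cell_pixels <- vector("list", n)
  for (k in seq_len(n)) {
    ca <- cos(angle[k]); sa <- sin(angle[k])
    ext <- ceiling(semi_a[k]) + 2L
    rows <- max(1L, floor(placed_y[k]) - ext):min(H, ceiling(placed_y[k]) + ext)
    cols <- max(1L, floor(placed_x[k]) - ext):min(W, ceiling(placed_x[k]) + ext)
    dy <- rows - placed_y[k]
    dx <- cols - placed_x[k]
    # rotated elliptical coordinates over the local grid (rows x cols)
    u <- outer(dy, dx, function(yy, xx) (xx * ca + yy * sa) / semi_a[k])
    v <- outer(dy, dx, function(yy, xx) (-xx * sa + yy * ca) / semi_b[k])
    rr <- sqrt(u^2 + v^2)
    inside <- rr <= 1
    if (!any(inside)) next
    sel <- which(inside, arr.ind = TRUE)
    gr <- rows[sel[, 1]]; gc <- cols[sel[, 2]]
    lin <- gr + (gc - 1L) * H
    take <- rr[inside] < rr_norm[lin]  # contested pixels go to the nearer cell
    lin <- lin[take]
    instance[lin] <- k
    rr_norm[lin] <- rr[inside][take]
    cell_pixels[[k]] <- NULL  # recomputed below after contention resolved
  }
  for (k in seq_len(n)) cell_pixels[[k]] <- which(instance == k)
  empty <- lengths(cell_pixels) == 0
  if (any(empty)) abort("internal error: a placed cell rasterized to zero pixels")

  label_mask <- label_components(instance > 0)
  comp_of_cell <- vapply(seq_len(n), function(k) {
    as.integer(label_mask[cell_pixels[[k]][1]])
  }, integer(1))

  # --- per-cell intensities ---------------------------------------------------
  base <- matrix(0, H * W, 3)  # per-channel noiseless cell image (flattened)
  rho_mu <- pmin(0.95, SYNTH_RHO_MEAN * cfg$joint_signal_strength)
  for (k in seq_len(n)) {
    pix <- cell_pixels[[k]]
    npx <- length(pix)
    cls <- labels[k]
    means <- vapply(GAD_CHANNELS, function(ch) {
      m <- cfg$channel_models[[ch]][[cls]]
      rnorm(1, m[["mean"]], m[["sd"]])
    }, numeric(1))
    means <- pmax(means, 500)
    # soft edge falloff, renormalized so the within-cell mean is preserved
    rrk <- rr_norm[pix]
    fall <- exp(-((pmax(rrk - 0.6, 0) / 0.45)^2))
    fall <- fall / mean(fall)
    # correlated textures for NeuN (ch2) and Nissl (ch3)
    sgn <- if (cls == "positive") 1 else -1
    rho <- max(-0.95, min(0.95, rnorm(1, sgn * rho_mu, SYNTH_RHO_SD)))
    f <- rnorm(npx); g <- rnorm(npx)
    u <- f
    v <- rho * f + sqrt(1 - rho^2) * g
    t1 <- rnorm(npx)  # independent texture for the GAD67 channel
    base[pix, 1] <- means[1] * fall + SYNTH_TEXTURE_SD * t1
    base[pix, 2] <- means[2] * fall + SYNTH_TEXTURE_SD * u
    base[pix, 3] <- means[3] * fall + SYNTH_TEXTURE_SD * v
  }

  # --- planes: gain drift + noise, quantized to 16-bit steps ------------------
  intens <- array(0, dim = c(H, W, cfg$n_planes, 3))
  gains <- matrix(runif(cfg$n_planes * 3, cfg$plane_drift[1], cfg$plane_drift[2]),
                  cfg$n_planes, 3)
  for (ch in 1:3) {
    b <- matrix(base[, ch], H, W)
    for (p in seq_len(cfg$n_planes)) {
      img <- gains[p, ch] * b + SYNTH_BACKGROUND +
        rnorm(H * W, 0, cfg$noise_sd)
      intens[, , p, ch] <- round(pmin(pmax(img, 0), 65535))
    }
  }
  dimnames(intens) <- list(NULL, NULL, NULL, GAD_CHANNELS)

  stack <- new_gad_stack(intens, GAD_CHANNELS)

  cells <- tibble::tibble(
    cell_id = seq_len(n),
    label = labels,
    centroid_x = placed_x, centroid_y = placed_y,
    area_px2 = lengths(cell_pixels),
    semi_major = semi_a, semi_minor = semi_b, angle = angle,
    pair_id = pair_id,
    component_label = comp_of_cell
  )
  annotations <- dplyr::select(cells, "cell_id", "label",
                               "centroid_x", "centroid_y", "area_px2")
  structure(
    list(stack = stack,
         truth = list(cells = cells, instance_mask = instance,
                      label_mask = label_mask),
         annotations = annotations,
         config = cfg),
    class = "gad_micrograph")
}

# construct a gad_stack from an h x w x planes x channels array
new_gad_stack <- function(intensities, channel_names) {
  assert_that(length(dim(intensities)) == 4, "intensities must be 4-D")
  assert_that(!anyDuplicated(channel_names), "channel names must be unique")
  d <- dim(intensities)
  ps <- tidyr::expand_grid(channel = channel_names,
                           plane = seq_len(d[3]))
  ps$mean <- purrr::pmap_dbl(ps, function(channel, plane) {
    mean(intensities[, , plane, match(channel, channel_names)])
  })
  ps$sd <- purrr::pmap_dbl(ps[1:2], function(channel, plane) {
    stats::sd(intensities[, , plane, match(channel, channel_names)])
  })
  structure(list(intensities = intensities, channel_names = channel_names,
                 plane_stats = ps),
            class = "gad_stack")
}

#' Extract one plane image from a stack
#' @param stack A `gad_stack`.
#' @param channel Channel name.
#' @param plane 1-based plane index.
#' @return A numeric matrix.
#' @export
plane_image <- function(stack, channel, plane) {
  ci <- match(channel, stack$channel_names)
  assert_that(!is.na(ci), paste0("channel not in stack: ", channel))
  assert_that(plane >= 1 && plane <= dim(stack$intensities)[3],
              "plane index out of range")
  stack$intensities[, , plane, ci]
}

#' @export
print.gad_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<gad_stack> %d x %d px, %d planes, channels: %s\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' @export
print.gad_micrograph <- function(x, ...) {
  print(x$stack)
  tab <- table(x$truth$cells$label)
  cat(sprintf("  %d cells (%s)\n", nrow(x$truth$cells),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

# --- fixture I/O -------------------------------------------------------------

#' Write a synthetic micrograph to disk as TIFF + CSV + JSON
#'
#' One multi-page 16-bit TIFF per channel, 16-bit TIFFs for the labeled
#' component mask and the per-cell instance mask, the annotation table as CSV
#' and the generating configuration as a JSON sidecar. A matching
#' [read_fixture()] round-trips the pixel data exactly.
#'
#' @param sim A `gad_micrograph` from [generate_micrograph()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(sim, out_dir) {
  assert_that(inherits(sim, "gad_micrograph"), "sim must be a gad_micrograph")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create directory: ", out_dir))
  paths <- c()
  d <- dim(sim$stack$intensities)
  for (ch in sim$stack$channel_names) {
    ci <- match(ch, sim$stack$channel_names)
    pages <- lapply(seq_len(d[3]), function(p) {
      sim$stack$intensities[, , p, ci] / 65535
    })
    f <- file.path(out_dir, paste0("channel_", ch, ".tif"))
    ok <- tryCatch(tiff::writeTIFF(pages, f, bits.per.sample = 16L),
                   error = function(e) {
                     abort(paste0("failed to write ", f, ": ", conditionMessage(e)))
                   })
    paths[paste0("channel_", ch)] <- f
  }
  f <- file.path(out_dir, "label_mask.tif")
  tiff::writeTIFF(sim$truth$label_mask / 65535, f, bits.per.sample = 16L)
  paths["label_mask"] <- f
  f <- file.path(out_dir, "instance_mask.tif")
  tiff::writeTIFF(sim$truth$instance_mask / 65535, f, bits.per.sample = 16L)
  paths["instance_mask"] <- f
  f <- file.path(out_dir, "annotations.csv")
  readr::write_csv(sim$annotations, f)
  paths["annotations"] <- f
  f <- file.path(out_dir, "config.json")
  cfg <- sim$config
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA)
  paths["config"] <- f
  invisible(paths)
}

#' Read a fixture directory written by [write_fixture()]
#' @param dir Directory containing the fixture files.
#' @return A list with `stack`, `label_mask`, `instance_mask`, `annotations`.
#' @export
read_fixture <- function(dir) {
  files <- list.files(dir, pattern = "^channel_.*\\.tif$", full.names = TRUE)
  assert_that(length(files) > 0, paste0("no channel TIFFs found in ", dir))
  chs <- sub("^channel_(.*)\\.tif$", "\\1", basename(files))
  ord <- order(match(chs, GAD_CHANNELS))
  files <- files[ord]; chs <- chs[ord]
  pages <- lapply(files, function(f) tiff::readTIFF(f, all = TRUE))
  n_planes <- length(pages[[1]])
  H <- nrow(pages[[1]][[1]]); W <- ncol(pages[[1]][[1]])
  intens <- array(0, dim = c(H, W, n_planes, length(chs)))
  for (ci in seq_along(chs)) {
    for (p in seq_len(n_planes)) {
      intens[, , p, ci] <- round(pages[[ci]][[p]] * 65535)
    }
  }
  dimnames(intens) <- list(NULL, NULL, NULL, chs)
  lm_f <- file.path(dir, "label_mask.tif")
  im_f <- file.path(dir, "instance_mask.tif")
  ann_f <- file.path(dir, "annotations.csv")
  out <- list(stack = new_gad_stack(intens, chs))
  if (file.exists(lm_f)) {
    out$label_mask <- matrix(as.integer(round(tiff::readTIFF(lm_f) * 65535)), H, W)
  }
  if (file.exists(im_f)) {
    out$instance_mask <- matrix(as.integer(round(tiff::readTIFF(im_f) * 65535)), H, W)
  }
  if (file.exists(ann_f)) {
    out$annotations <- readr::read_csv(ann_f, show_col_types = FALSE)
  }
  out
}
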