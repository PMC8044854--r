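# Preprocessing: plane selection, per-plane normalization, segmentation,
# erosion-dilation instance splitting, area filtering, ROI statistics, crops.

#' Preprocessing configuration
#'
#' @param min_area Minimum ROI area in px^2; regions *smaller* than this are
#'   discarded (strict `<`, so `area == min_area` survives). Applied both
#'   before and after splitting.
#' @param planes_used 1-based plane indices to process; `NULL` means the first
#'   and the last plane of the stack.
#' @param erosion_radius Radius of the structuring element (a city-block
#'   disc, i.e. a diamond) used by the erosion-dilation splitter.
#' @param max_erosion_iters Iteration budget for the splitter.
#' @param detection_channel Channel the fallback segmenter thresholds
#'   (NeuN: the pan-neuronal channel in which every soma is bright).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(min_area = 180,
                              planes_used = NULL,
                              erosion_radius = 1,
                              max_erosion_iters = 10,
                              detection_channel = "NeuN") {
  assert_that(min_area > 0, "min_area must be positive")
  structure(list(min_area = min_area, planes_used = planes_used,
                 erosion_radius = as.integer(erosion_radius),
                 max_erosion_iters = as.integer(max_erosion_iters),
                 detection_channel = detection_channel),
            class = "preprocess_config")
}

#' Select z-planes from a stack
#'
#' Defaults to the first and the last plane. Duplicate indices (e.g. a
#' single-plane stack where first == last) are collapsed.
#'
#' @param stack A `gad_stack`.
#' @param config A [preprocess_config()].
#' @return A tibble with columns `channel`, `plane` and list-column `image`.
#' @export
extract_planes <- function(stack, config = preprocess_config()) {
  n_planes <- dim(stack$intensities)[3]
  planes <- config$planes_used %||% unique(c(1L, n_planes))
  planes <- as.integer(planes)
  assert_that(all(planes >= 1 & planes <= n_planes), "plane index out of range")
  planes <- unique(planes)
  out <- tidyr::expand_grid(channel = stack$channel_names, plane = planes)
  out$image <- purrr::pmap(out, function(channel, plane) {
    plane_image(stack, channel, plane)
  })
  out
}

#' Normalize one plane image
#'
#' Affine map sending `mean - SD` to 0 and `mean + SD` to 1, where the mean
#' and SD are taken over every pixel of the plane. Values outside `[0, 1]`
#' are kept (no clipping); the output mean is exactly 0.5. A constant plane
#' (SD = 0) returns all 0.5 with a warning.
#'
#' @param plane A numeric matrix of raw intensities.
#' @return A numeric matrix of normalized values.
#' @export
normalize_plane <- function(plane) {
  assert_that(is.matrix(plane) && length(plane) > 0, "plane must be a nonempty matrix")
  m <- mean(plane)
  s <- stats::sd(plane)
  if (!is.finite(s) || s == 0) {
    warn("constant plane (SD = 0): returning all 0.5")
    return(matrix(0.5, nrow(plane), ncol(plane)))
  }
  (plane - (m - s)) / (2 * s)
}

#' Segment cells in a plane
#'
#' If an external mask is supplied (e.g. produced by a pre-trained U-Net run
#' outside this package) it is passed through, only relabeled to consecutive
#' positive integers; a strictly binary mask is first connected-component
#' labeled. Otherwise a simple internal fallback is used: Otsu threshold on
#' the detection channel, hole filling, component labeling.
#'
#' @param plane Numeric matrix (the detection-channel plane, used only by the
#'   fallback).
#' @param external_mask Optional integer/binary matrix aligned to `plane`.
#' @param plane_index Plane index recorded in the result.
#' @return A list of class `gad_mask` with `labels`, `source`, `plane_index`.
#' @export
segment_cells <- function(plane, external_mask = NULL, plane_index = 1L) {
  if (!is.null(external_mask)) {
    assert_that(all(dim(external_mask) == dim(plane)),
                "external mask shape does not match the plane")
    vals <- sort(unique(as.integer(external_mask[external_mask > 0])))
    if (length(vals) <= 1) {
      labels <- label_components(external_mask > 0)
    } else {
      labels <- matrix(match(as.integer(external_mask), vals, nomatch = 0L),
                       nrow(external_mask), ncol(external_mask))
    }
    src <- "external-mask"
  } else {
    rng <- range(plane)
    scaled <- if (diff(rng) > 0) (plane - rng[1]) / diff(rng) else plane * 0
    thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    bin <- EBImage::fillHull(EBImage::Image(scaled > thr))
    labels <- label_components(matrix(as.numeric(bin), nrow(plane), ncol(plane)))
    src <- "internal-fallback"
  }
  structure(list(labels = labels, source = src, plane_index = plane_index),
            class = "gad_mask")
}

# city-block disc (diamond) structuring element of the configured radius;
# it erodes diagonal necks faster than it consumes round somata, which is
# what makes waist-first splitting of fused cell pairs work
erosion_brush <- function(radius) {
  EBImage::makeBrush(2L * radius + 1L, shape = "diamond")
}

# one ROI record from a patch (logical matrix) + 0-based offset
make_roi <- function(patch, r0, c0, parent_label, plane_index, lineage = NA_integer_) {
  bb <- mask_bbox(patch)
  patch <- patch[(bb["r"] + 1):(bb["r"] + bb["h"]),
                 (bb["c"] + 1):(bb["c"] + bb["w"]), drop = FALSE]
  area <- sum(patch)
  per <- cpp_trace_perimeter(patch)
  if (!is.finite(per) || per < 1) {
    # degenerate (single-pixel-ish) region: report the equal-area disc
    per <- 2 * sqrt(pi * area)
  }
  tibble::tibble(
    parent_label = as.integer(parent_label),
    plane = as.integer(plane_index),
    split_lineage = as.integer(lineage),
    area = as.integer(area),
    perimeter = per,
    circularity = 4 * pi * area / per^2,
    bb_r = as.integer(r0 + bb["r"]), bb_c = as.integer(c0 + bb["c"]),
    bb_h = as.integer(bb["h"]), bb_w = as.integer(bb["w"]),
    patch = list(patch)
  )
}

#' Split fused ROIs by iterated erosion and dilation
#'
#' Each labeled region is eroded with a small structuring element until it
#' separates into more than one connected component (or vanishes, or the
#' iteration budget is hit). The resulting components are dilated back by the
#' same number of iterations and intersected with the original region, so no
#' child extends beyond its parent; pixels claimed by several dilated
#' children go to the nearest child (ties to the lower child id). Intensity
#' images are never touched -- only region membership changes.
#'
#' @param mask A `gad_mask` (or labeled integer matrix).
#' @param config A [preprocess_config()].
#' @return A tibble of ROIs with geometry columns (`area`, `perimeter`,
#'   `circularity`, 0-based half-open bounding box `bb_r`, `bb_c`, `bb_h`,
#'   `bb_w`), `split_lineage` (the parent label for split children, `NA` for
#'   pass-through regions) and list-column `patch`.
#' @export
split_rois_erosion_dilation <- function(mask, config = preprocess_config()) {
  labels <- if (inherits(mask, "gad_mask")) mask$labels else mask
  plane_index <- if (inherits(mask, "gad_mask")) mask$plane_index else 1L
  n_lab <- max(labels)
  out <- vector("list", n_lab)
  if (n_lab == 0) {
    return(empty_roi_tbl())
  }
  brush <- erosion_brush(config$erosion_radius)
  pad <- config$max_erosion_iters * config$erosion_radius + 1L
  for (L in seq_len(n_lab)) {
    sel <- labels == L
    if (!any(sel)) next
    bb <- mask_bbox(sel)
    r0 <- max(0L, bb["r"] - pad); c0 <- max(0L, bb["c"] - pad)
    r1 <- min(nrow(labels), bb["r"] + bb["h"] + pad)
    c1 <- min(ncol(labels), bb["c"] + bb["w"] + pad)
    parent <- sel[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
    children <- split_one_region(parent, brush, config$max_erosion_iters)
    if (is.null(children)) {
      out[[L]] <- make_roi(parent, r0, c0, L, plane_index)
    } else {
      out[[L]] <- dplyr::bind_rows(lapply(children, function(ch) {
        make_roi(ch, r0, c0, L, plane_index, lineage = L)
      }))
    }
  }
  res <- dplyr::bind_rows(out)
  res$roi_id <- seq_len(nrow(res))
  dplyr::relocate(res, "roi_id")
}

# core of the splitter: returns NULL if the region stays whole, else a list
# of child logical matrices (same dims as parent)
split_one_region <- function(parent, brush, max_iters) {
  img <- EBImage::Image(parent * 1)
  k <- 0L
  repeat {
    if (k >= max_iters) return(NULL)
    img <- EBImage::erode(img, brush)
    k <- k + 1L
    m <- matrix(as.numeric(img), nrow(parent), ncol(parent))
    if (!any(m > 0)) return(NULL)  # vanished: keep the original region
    comp <- label_components(m > 0)
    ncomp <- max(comp)
    if (ncomp > 1) {
      # dilate each core back k iterations, clip to the parent support
      cores <- lapply(seq_len(ncomp), function(i) comp == i)
      dil <- lapply(cores, function(core) {
        d <- EBImage::Image(core * 1)
        for (it in seq_len(k)) d <- EBImage::dilate(d, brush)
        (matrix(as.numeric(d), nrow(parent), ncol(parent)) > 0) & parent
      })
      claim <- Reduce(`+`, lapply(dil, function(x) x * 1))
      contested <- claim > 1
      if (any(contested)) {
        # distance of every pixel to each child's eroded core
        dists <- lapply(cores, function(core) {
          dm <- EBImage::distmap(EBImage::Image(1 - core * 1))
          matrix(as.numeric(dm), nrow(parent), ncol(parent))
        })
        idx <- which(contested)
        dmat <- vapply(dists, function(d) d[idx], numeric(length(idx)))
        dmat <- matrix(dmat, nrow = length(idx))
        winner <- apply(dmat, 1, which.min)  # ties: lower child id
        for (i in seq_len(ncomp)) {
          lose <- idx[winner != i]
          dil[[i]][lose] <- FALSE
        }
      }
      dil <- dil[vapply(dil, any, logical(1))]
      if (length(dil) <= 1) return(NULL)
      return(dil)
    }
  }
}

empty_roi_tbl <- function() {
  tibble::tibble(roi_id = integer(), parent_label = integer(), plane = integer(),
                 split_lineage = integer(), area = integer(), perimeter = double(),
                 circularity = double(), bb_r = integer(), bb_c = integer(),
                 bb_h = integer(), bb_w = integer(), patch = list())
}

#' Filter ROIs by area
#'
#' Keeps ROIs whose area is at least `min_area` px^2 (regions *smaller* than
#' the threshold are excluded; the boundary value survives). Order preserved.
#'
#' @param rois ROI tibble from [split_rois_erosion_dilation()].
#' @param config A [preprocess_config()] (or a bare number via `min_area`).
#' @param min_area Optional override of `config$min_area`.
#' @return The filtered ROI tibble.
#' @export
filter_rois_by_area <- function(rois, config = preprocess_config(),
                                min_area = NULL) {
  thr <- min_area %||% config$min_area
  dplyr::filter(rois, .data$area >= thr)
}

#' Per-ROI intensity and shape statistics
#'
#' Mean fluorescence per channel is computed on the *raw* (pre-normalization)
#' plane of each ROI, alongside area, perimeter and circularity
#' (`4 * pi * area / perimeter^2` under the package's contour-tracing
#' perimeter estimator with diagonal correction).
#'
#' @param rois ROI tibble.
#' @param stack A `gad_stack` providing raw planes.
#' @param channels Channels to average; default all in the stack.
#' @return A tibble: `roi_id`, `plane`, `area`, `perimeter`, `circularity`,
#'   and one `mean_<channel>` column per channel.
#' @export
compute_roi_stats <- function(rois, stack, channels = NULL) {
  channels <- channels %||% stack$channel_names
  assert_that(nrow(rois) > 0, "empty ROI table")
  out <- dplyr::select(rois, "roi_id", "plane", "area", "perimeter", "circularity")
  for (ch in channels) {
    out[[paste0("mean_", ch)]] <- purrr::pmap_dbl(
      list(rois$patch, rois$bb_r, rois$bb_c, rois$plane),
      function(patch, r0, c0, p) {
        img <- plane_image(stack, ch, p)
        sub <- img[(r0 + 1):(r0 + nrow(patch)), (c0 + 1):(c0 + ncol(patch)),
                   drop = FALSE]
        mean(sub[patch])
      })
  }
  out
}

#' Crop rectangular cell images from normalized planes
#'
#' Each crop is the tight bounding-box rectangle of an ROI (full rectangle,
#' not masked to the ROI), taken from the normalized planes of the selected
#' channels.
#'
#' @param rois ROI tibble (after area filtering).
#' @param norm_planes Tibble from [extract_planes()] whose `image` entries
#'   have been normalized (see [normalize_plane()]).
#' @param channels Channel subset (canonical order is enforced).
#' @return A tibble of cell images: `roi_id`, `plane`, `h`, `w` and
#'   list-column `crop` (arrays `h x w x n_channels`), with a `channels`
#'   attribute.
#' @export
crop_cell_images <- function(rois, norm_planes, channels = NULL) {
  channels <- canonical_channels(channels %||% unique(norm_planes$channel),
                                 unique(norm_planes$channel))
  assert_that(length(channels) > 0, "channel subset must be nonempty")
  assert_that(all(rois$bb_h > 0 & rois$bb_w > 0), "degenerate bounding box")
  crops <- purrr::pmap(
    dplyr::select(rois, "bb_r", "bb_c", "bb_h", "bb_w", "plane"),
    function(bb_r, bb_c, bb_h, bb_w, plane) {
      arr <- array(0, dim = c(bb_h, bb_w, length(channels)))
      for (ci in seq_along(channels)) {
        img <- norm_planes$image[[which(norm_planes$channel == channels[ci] &
                                          norm_planes$plane == plane)]]
        arr[, , ci] <- img[(bb_r + 1):(bb_r + bb_h), (bb_c + 1):(bb_c + bb_w)]
      }
      arr
    })
  out <- tibble::tibble(roi_id = rois$roi_id, plane = rois$plane,
                        h = rois$bb_h, w = rois$bb_w, crop = crops)
  attr(out, "channels") <- channels
  out
}

#' Full preprocessing pipeline for one micrograph
#'
#' Selects planes, segments (external masks or the internal fallback), splits
#' fused regions, filters by area, computes raw-intensity ROI statistics,
#' normalizes the selected planes and crops cell images. ROIs of different
#' planes are linked into cells by pixel overlap, and -- when ground truth is
#' available -- each cell is annotated by majority overlap with the true
#' per-cell instance mask.
#'
#' @param stack A `gad_stack`.
#' @param masks Optional external segmentation: a single labeled matrix
#'   (reused for every selected plane) or a list of matrices, one per
#'   selected plane.
#' @param truth Optional ground truth (`$instance_mask` + `$cells`) used to
#'   attach class labels.
#' @param config A [preprocess_config()].
#' @return A list of class `gad_cells`: `crops` (cell-image tibble with
#'   `cell_id`, `label`, `sample_weight`), `rois`, `stats`.
#' @export
preprocess_micrograph <- function(stack, masks = NULL, truth = NULL,
                                  config = preprocess_config()) {
  planes_tbl <- extract_planes(stack, config)
  planes <- unique(planes_tbl$plane)
  all_rois <- vector("list", length(planes))
  for (pi in seq_along(planes)) {
    p <- planes[pi]
    det <- planes_tbl$image[[which(planes_tbl$channel == config$detection_channel &
                                     planes_tbl$plane == p)]]
    ext <- NULL
    if (!is.null(masks)) {
      ext <- if (is.list(masks)) masks[[pi]] else masks
    }
    m <- segment_cells(det, external_mask = ext, plane_index = p)
    rois <- split_rois_erosion_dilation(m, config)
    # the area filter is applied both to raw and to split regions; children
    # carry split_lineage so pre-split survivors are those with NA lineage
    rois <- filter_rois_by_area(rois, config)
    all_rois[[pi]] <- rois
  }
  rois <- dplyr::bind_rows(all_rois)
  if (nrow(rois) > 0) rois$roi_id <- seq_len(nrow(rois))
  norm_tbl <- planes_tbl
  norm_tbl$image <- lapply(planes_tbl$image, normalize_plane)
  crops <- crop_cell_images(rois, norm_tbl)
  stats <- if (nrow(rois) > 0) compute_roi_stats(rois, stack) else NULL
  cells <- link_cells(rois, dim(stack$intensities)[1:2])
  crops$cell_id <- cells
  if (!is.null(truth)) {
    ann <- annotate_rois(rois, truth)
    crops$label <- ann$label
    if (!is.null(stats)) stats$label <- ann$label
  } else {
    crops$label <- NA_character_
  }
  crops$sample_weight <- 1
  structure(list(crops = crops, rois = rois, stats = stats,
                 channels = attr(crops, "channels")),
            class = "gad_cells")
}

# link ROIs across planes into physical cells by pixel overlap;
# returns an integer cell id per ROI row
link_cells <- function(rois, img_dim) {
  if (nrow(rois) == 0) return(integer(0))
  planes <- sort(unique(rois$plane))
  cell_id <- rep(NA_integer_, nrow(rois))
  ref_rows <- which(rois$plane == planes[1])
  cell_id[ref_rows] <- seq_along(ref_rows)
  next_id <- length(ref_rows)
  if (length(planes) > 1) {
    # paint the reference plane's ROIs into a label image once
    ref_img <- matrix(0L, img_dim[1], img_dim[2])
    for (i in seq_along(ref_rows)) {
      r <- ref_rows[i]
      patch <- rois$patch[[r]]
      rr <- (rois$bb_r[r] + 1):(rois$bb_r[r] + rois$bb_h[r])
      cc <- (rois$bb_c[r] + 1):(rois$bb_c[r] + rois$bb_w[r])
      sub <- ref_img[rr, cc, drop = FALSE]
      sub[patch] <- i
      ref_img[rr, cc] <- sub
    }
    for (p in planes[-1]) {
      for (r in which(rois$plane == p)) {
        patch <- rois$patch[[r]]
        rr <- (rois$bb_r[r] + 1):(rois$bb_r[r] + rois$bb_h[r])
        cc <- (rois$bb_c[r] + 1):(rois$bb_c[r] + rois$bb_w[r])
        hits <- ref_img[rr, cc][patch]
        hits <- hits[hits > 0]
        if (length(hits) > 0.3 * rois$area[r]) {
          best <- as.integer(names(sort(table(hits), decreasing = TRUE))[1])
          cell_id[r] <- cell_id[ref_rows[best]]
        } else {
          next_id <- next_id + 1L
          cell_id[r] <- next_id
        }
      }
    }
  }
  cell_id
}

# majority-overlap annotation of ROIs against a ground-truth instance mask
annotate_rois <- function(rois, truth) {
  labs <- character(nrow(rois))
  truth_cell <- rep(NA_integer_, nrow(rois))
  for (r in seq_len(nrow(rois))) {
    patch <- rois$patch[[r]]
    rr <- (rois$bb_r[r] + 1):(rois$bb_r[r] + rois$bb_h[r])
    cc <- (rois$bb_c[r] + 1):(rois$bb_c[r] + rois$bb_w[r])
    ids <- truth$instance_mask[rr, cc][patch]
    ids <- ids[ids > 0]
    if (length(ids) == 0) {
      labs[r] <- "unknown"
    } else {
      best <- as.integer(names(sort(table(ids), decreasing = TRUE))[1])
      truth_cell[r] <- best
      labs[r] <- truth$cells$label[truth$cells$cell_id == best]
    }
  }
  list(label = labs, truth_cell = truth_cell)
}

#' @export
print.gad_cells <- function(x, ...) {
  cat(sprintf("<gad_cells> %d cell images from %d ROIs (channels: %s)\n",
              nrow(x$crops), nrow(x$rois), paste(x$channels, collapse = ", ")))
  invisible(x)
}
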