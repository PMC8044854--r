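# internal helpers ----------------------------------------------------------

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

#' Order channel names canonically (GAD67, NeuN, Nissl)
#'
#' @param channels Character vector of channel names.
#' @param available Universe of valid names, in canonical order.
#' @return The unique channels of `channels`, canonically ordered.
#' @export
canonical_channels <- function(channels, available = GAD_CHANNELS) {
  channels <- unique(channels)
  bad <- setdiff(channels, available)
  if (length(bad) > 0) {
    abort(paste0("unknown channel(s): ", paste(bad, collapse = ", ")))
  }
  available[available %in% channels]
}

combo_label <- function(channels) paste(channels, collapse = "+")

# derive a child seed (< 2^31) from a base seed and a stream index
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + 104729 * as.double(stream)) %% 2147483647 + 1
}

# connected-component labeling; 8-connectivity for foreground throughout
label_components <- function(mask) {
  cpp_label8(matrix(as.logical(mask > 0), nrow(mask), ncol(mask)))
}

# tight bounding box of a logical matrix, 0-based half-open (r, c, h, w)
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]) - 1L
  c0 <- min(idx[, 2]) - 1L
  c(r = r0, c = c0,
    h = max(idx[, 1]) - r0, w = max(idx[, 2]) - c0)
}
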