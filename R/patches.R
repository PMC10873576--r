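#' Random patch extraction
#'
#' Crops `count` square patches of side `size` from an image, with top-left
#' corners drawn uniformly (with replacement) over all valid positions.
#' Reproducible: a fixed `seed` always yields the same patch positions.
#' Patches of shape `channels x 192 x 192` are the training unit for the
#' convolutional predictor protocol; the linear backend does not need them.
#'
#' @param img A `multichannel_image`.
#' @param size Patch side length in pixels; must not exceed either image side.
#' @param count Number of patches.
#' @param seed Integer seed for the patch positions.
#' @return A list of `multichannel_image` patches, each with a `position`
#'   attribute `c(row, col)` (0-based top-left corner).
#' @export
random_patches <- function(img, size, count, seed) {
  d <- image_dim(img)
  size <- as.integer(size)
  if (size > min(d)) {
    abort(sprintf("patch size %d exceeds image dimensions %d x %d",
                  size, d[1], d[2]))
  }
  offs <- with_rng(seed, {
    cbind(
      sample.int(d[1] - size + 1L, count, replace = TRUE) - 1L,
      sample.int(d[2] - size + 1L, count, replace = TRUE) - 1L
    )
  })
  lapply(seq_len(count), function(i) {
    crop_patch(img, offs[i, 1], offs[i, 2], size)
  })
}

crop_patch <- function(img, row0, col0, size) {
  p <- multichannel_image(
    img$pixels[, row0 + seq_len(size), col0 + seq_len(size), drop = FALSE],
    img$channel_names, img$normalized
  )
  attr(p, "position") <- c(row = row0, col = col0)
  p
}

#' Sliding-window tiling
#'
#' Tiles an image with non-overlapping `size x size` patches at stride
#' `size`; when the image side is not a multiple of `size`, the final
#' row/column of patches is re-anchored to end at the image border so that
#' the union of patches covers every pixel (those patches overlap their
#' neighbours). Used for whole-image inference: predict each tile, then
#' [stitch_patches()] the results back together.
#'
#' @inheritParams random_patches
#' @return A list of patches as in [random_patches()], each carrying its
#'   0-based `position` attribute.
#' @export
tile_patches <- function(img, size) {
  d <- image_dim(img)
  size <- as.integer(size)
  if (size > min(d)) {
    abort(sprintf("patch size %d exceeds image dimensions %d x %d",
                  size, d[1], d[2]))
  }
  anchors <- function(n) {
    a <- seq.int(0L, n - size, by = size)
    if (a[length(a)] + size < n) a <- c(a, n - size)
    a
  }
  rows <- anchors(d[1])
  cols <- anchors(d[2])
  out <- vector("list", length(rows) * length(cols))
  k <- 1L
  for (r in rows) {
    for (cc in cols) {
      out[[k]] <- crop_patch(img, r, cc, size)
      k <- k + 1L
    }
  }
  out
}

#' Stitch patches back into a full image
#'
#' Reassembles patches (as produced by [tile_patches()], possibly with their
#' pixel values replaced by model predictions) onto a `height x width`
#' canvas. Pixels covered by several patches receive the mean of the
#' contributions; `stitch_patches(tile_patches(img, s), h, w)` reproduces
#' `img` exactly. Uncovered pixels are an error.
#'
#' @param patches List of `multichannel_image` patches with `position`
#'   attributes (0-based top-left corners).
#' @param height,width Canvas dimensions.
#' @return A `multichannel_image`.
#' @export
stitch_patches <- function(patches, height, width) {
  if (!length(patches)) abort("no patches to stitch")
  nc <- n_channels(patches[[1]])
  nm <- channel_names(patches[[1]])
  acc <- array(0, c(nc, height, width))
  cnt <- matrix(0, height, width)
  for (p in patches) {
    pos <- attr(p, "position")
    if (is.null(pos)) abort("patch lacks a position attribute")
    d <- image_dim(p)
    ri <- pos[[1]] + seq_len(d[1])
    ci <- pos[[2]] + seq_len(d[2])
    if (max(ri) > height || max(ci) > width) {
      abort("patch extends beyond the canvas")
    }
    acc[, ri, ci] <- acc[, ri, ci, drop = FALSE] + p$pixels
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  if (any(cnt == 0)) {
    gap <- which(cnt == 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "patches do not cover the canvas: pixel (%d, %d) is uncovered",
      gap[1], gap[2]
    ))
  }
  for (i in seq_len(nc)) {
    acc[i, , ] <- acc[i, , ] / cnt
  }
  multichannel_image(acc, nm, patches[[1]]$normalized)
}
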