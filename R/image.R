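#' Multichannel image container
#'
#' A `multichannel_image` wraps a numeric `channels x height x width` array
#' together with unique channel (marker) names and a flag recording which
#' normalization recipe, if any, has been applied. It is the unit of data for
#' every image operation in the package: one object per tissue region, one
#' channel per marker.
#'
#' @param pixels Numeric array of shape `channels x height x width` (a plain
#'   `height x width` matrix is promoted to a single channel).
#' @param channel_names Character vector of unique marker identifiers, one per
#'   channel.
#' @param normalized One of `"none"`, `"arcsinh_z"`, `"clip_blur_z"`, `"z"`;
#'   which normalization recipe produced the pixel values.
#' @return A `multichannel_image` object.
#' @examples
#' img <- multichannel_image(array(rnorm(3 * 8 * 8), c(3, 8, 8)),
#'                           c("CD3", "CD4", "CD8"))
#' channel_names(img)
#' @export
multichannel_image <- function(pixels, channel_names,
                               normalized = c("none", "arcsinh_z",
                                              "clip_blur_z", "z")) {
  normalized <- match.arg(normalized)
  if (is.matrix(pixels)) {
    pixels <- array(pixels, c(1L, nrow(pixels), ncol(pixels)))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    abort("pixels must be a channels x height x width array")
  }
  if (!is.numeric(pixels)) {
    abort("pixels must be numeric")
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(pixels)[1]) {
    abort(sprintf(
      "channel name count (%d) does not match channel count (%d)",
      length(channel_names), dim(pixels)[1]
    ))
  }
  if (anyDuplicated(channel_names)) {
    abort("channel names must be unique")
  }
  if (dim(pixels)[2] < 1 || dim(pixels)[3] < 1) {
    abort("image height and width must be at least 1")
  }
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, channel_names = channel_names,
         normalized = normalized),
    class = "multichannel_image"
  )
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<multichannel_image> %d channels, %d x %d pixels, normalized = %s\n",
    d[1], d[2], d[3], x$normalized
  ))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname multichannel_image
#' @param img,x A `multichannel_image`.
#' @export
channel_names <- function(img) img$channel_names

#' @rdname multichannel_image
#' @export
n_channels <- function(img) dim(img$pixels)[1]

#' @rdname multichannel_image
#' @export
image_dim <- function(img) dim(img$pixels)[2:3]

#' @rdname multichannel_image
#' @export
is_multichannel_image <- function(x) inherits(x, "multichannel_image")

#' Extract one channel as a matrix
#'
#' @param img A `multichannel_image`.
#' @param channel Channel name or index.
#' @return A `height x width` numeric matrix.
#' @export
get_channel <- function(img, channel) {
  idx <- resolve_channel(img, channel)
  img$pixels[idx, , , drop = TRUE]
}

resolve_channel <- function(img, channel) {
  if (is.character(channel)) {
    idx <- match(channel, img$channel_names)
    if (anyNA(idx)) {
      abort(sprintf("channel not found: %s",
                    paste(channel[is.na(idx)], collapse = ", ")))
    }
    idx
  } else {
    channel <- as.integer(channel)
    if (any(channel < 1 | channel > n_channels(img))) {
      abort("channel index out of range")
    }
    channel
  }
}

#' Restrict an image to a subset of channels
#'
#' @param img A `multichannel_image`.
#' @param channels Character vector of channel names (order is honoured).
#' @return A `multichannel_image` with only the requested channels.
#' @export
subset_channels <- function(img, channels) {
  idx <- resolve_channel(img, channels)
  multichannel_image(img$pixels[idx, , , drop = FALSE],
                     img$channel_names[idx], img$normalized)
}

# ---- float32 <-> 32-bit TIFF sample packing --------------------------------
#
# r-tiff stores 32-bit samples as unsigned integers scaled from [0,1]; values
# outside [0,1] are undefined. To keep float pixels bit-exact through a TIFF
# round trip, each pixel's float32 bit pattern is stored verbatim as a 32-bit
# sample: k/(2^32-1) survives round(x * (2^32-1)) exactly for every k.

float_to_unit <- function(x) {
  bits <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                  "integer", n = length(x), size = 4L)
  k <- as.numeric(bits)
  k[k < 0] <- k[k < 0] + 4294967296
  k / 4294967295
}

int_to_float <- function(k) {
  readBin(writeBin(as.integer(k), raw(), size = 4L),
          "numeric", n = length(k), size = 4L)
}

as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L),
          "numeric", n = length(x), size = 4L)
}

sidecar_path <- function(path) paste0(path, ".channels.csv")

#' Read a multichannel TIFF image
#'
#' Reads a multi-page TIFF (one page per marker channel) together with its
#' channel names. Names are taken, in order of precedence, from the `names`
#' argument, or from a sidecar two-column CSV (`index,name`) written next to
#' the image by [write_multichannel()].
#'
#' Pixels written by [write_multichannel()] are stored at float32 precision
#' and round-trip bit-exactly at that precision.
#'
#' @param path Path to a multi-page TIFF file.
#' @param names Optional character vector of channel names, or a data frame
#'   with columns `index` and `name`.
#' @return A `multichannel_image` with `normalized = "none"`.
#' @export
read_multichannel <- function(path, names = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("image file not found: %s", path))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]])
  w <- ncol(pages[[1]])
  pix <- array(0, c(length(pages), h, w))
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (!is.numeric(pg)) abort("non-numeric pixel data in TIFF page")
    pix[i, , ] <- matrix(int_to_float(as.vector(pg)), h, w)
  }
  if (is.data.frame(names)) {
    names <- names$name[order(names$index)]
  }
  if (is.null(names)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      tab <- utils::read.csv(sc, stringsAsFactors = FALSE)
      names <- tab$name[order(tab$index)]
    } else {
      abort("no channel names supplied and no sidecar channel table found")
    }
  }
  multichannel_image(pix, names, "none")
}

#' Write a multichannel TIFF image
#'
#' Writes one TIFF page per channel plus a sidecar `index,name` CSV carrying
#' the channel names. Pixels are stored at float32 precision (bit-exact
#' round trip via [read_multichannel()]).
#'
#' @param img A `multichannel_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multichannel <- function(img, path) {
  if (!is_multichannel_image(img)) abort("img must be a multichannel_image")
  if (n_channels(img) < 1) abort("image has no channels")
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("directory does not exist: %s", dir))
  pages <- lapply(seq_len(n_channels(img)), function(i) {
    ch <- img$pixels[i, , , drop = TRUE]
    if (!is.matrix(ch)) ch <- matrix(ch, image_dim(img)[1], image_dim(img)[2])
    matrix(float_to_unit(ch), nrow(ch), ncol(ch))
  })
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                        compression = "none")
  if (!ok) abort(sprintf("failed to write TIFF: %s", path))
  utils::write.csv(
    data.frame(index = seq_along(img$channel_names),
               name = img$channel_names),
    sidecar_path(path),
    row.names = FALSE
  )
  invisible(path)
}

#' Cell label masks
#'
#' A `cell_mask` is an integer `height x width` label matrix: 0 marks
#' background, `k >= 1` marks pixels of cell `k`. Masks pair with a
#' `multichannel_image` of the same spatial shape for single-cell evaluation.
#'
#' @param labels Integer matrix of cell labels.
#' @return A `cell_mask` object.
#' @export
cell_mask <- function(labels) {
  if (!is.matrix(labels)) abort("labels must be a matrix")
  lab <- as.integer(round(labels))
  if (any(lab < 0)) abort("cell labels must be nonnegative")
  m <- matrix(lab, nrow(labels), ncol(labels))
  structure(list(labels = m), class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d x %d pixels, %d cells\n",
              nrow(x$labels), ncol(x$labels),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Read / write integer-label cell masks as TIFF
#'
#' @param path File path.
#' @return `read_cell_mask()` returns a `cell_mask`; `write_cell_mask()`
#'   returns `path` invisibly.
#' @export
read_cell_mask <- function(path) {
  if (!file.exists(path)) abort(sprintf("mask file not found: %s", path))
  pg <- tiff::readTIFF(path, as.is = TRUE)
  cell_mask(matrix(as.integer(pg), nrow(pg), ncol(pg)))
}

#' @rdname read_cell_mask
#' @param mask A `cell_mask`.
#' @export
write_cell_mask <- function(mask, path) {
  lab <- mask$labels
  ok <- tiff::writeTIFF(matrix(as.numeric(lab) / 4294967295,
                               nrow(lab), ncol(lab)),
                        path, bits.per.sample = 32L, reduce = FALSE,
                        compression = "none")
  if (!ok) abort(sprintf("failed to write mask TIFF: %s", path))
  invisible(path)
}
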