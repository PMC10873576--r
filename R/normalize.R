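#' Channel normalization recipes
#'
#' Three per-channel normalization recipes used for different imaging
#' modalities, all ending in a z-score so that channel intensities are
#' comparable and prediction errors live on a common scale:
#'
#' * `normalize_arcsinh_z()` (CODEX): each channel is divided by
#'   `max(5 * q20, 15)` where `q20` is its 20th percentile, arcsinh
#'   transformed (variance stabilization for antibody counts), then z-scored.
#' * `normalize_clip_blur_z()` (IMC): each channel is clipped to
#'   `[0, q98+]` where `q98+` is the 98th percentile of its positive pixel
#'   values, Gaussian-blurred (`sigma = 1.5` pixels, reflective boundaries),
#'   then z-scored; IMC's shot noise motivates the blur.
#' * `normalize_z()`: plain per-channel z-score, for weak/sparse signals.
#'
#' All z-scores use the population standard deviation (divide by `n`). If a
#' channel's standard deviation falls below `1e-12` the channel is set to all
#' zeros and a warning is emitted instead of dividing (the "sigma guard"):
#' constant channels occur in degenerate fixtures.
#'
#' @param img A `multichannel_image` with `normalized = "none"`.
#' @param q_positive_only Logical; compute the 20th percentile over positive
#'   pixels only instead of all pixels (default `FALSE`, all pixels).
#' @return A `multichannel_image` with the recipe recorded in `$normalized`.
#' @name normalization
NULL

zscore_channel <- function(ch, channel_name) {
  s <- sd_pop(ch)
  if (s < 1e-12) {
    warn(sprintf(
      "channel '%s' has (near-)zero variance; sigma guard produced zeros",
      channel_name
    ), class = "panelpick_sigma_guard")
    ch[] <- 0
    ch
  } else {
    (ch - mean(ch)) / s
  }
}

check_unnormalized <- function(img) {
  if (!is_multichannel_image(img)) abort("img must be a multichannel_image")
  if (img$normalized != "none") {
    abort(sprintf("image is already normalized (recipe: %s)", img$normalized))
  }
}

#' @rdname normalization
#' @export
normalize_arcsinh_z <- function(img, q_positive_only = FALSE) {
  check_unnormalized(img)
  out <- img$pixels
  for (i in seq_len(n_channels(img))) {
    ch <- out[i, , ]
    px <- as.vector(ch)
    if (q_positive_only) px <- px[px > 0]
    q20 <- if (length(px)) percentile(px, 20) else 0
    divisor <- max(5 * q20, 15)
    ch <- asinh(ch / divisor)
    out[i, , ] <- zscore_channel(ch, img$channel_names[i])
  }
  multichannel_image(out, img$channel_names, "arcsinh_z")
}

#' @rdname normalization
#' @param clip_percentile Percentile (of positive pixel values) used as the
#'   upper clip bound; default 98.
#' @param sigma Gaussian blur standard deviation in pixels; default 1.5.
#' @export
normalize_clip_blur_z <- function(img, clip_percentile = 98, sigma = 1.5) {
  check_unnormalized(img)
  out <- img$pixels
  for (i in seq_len(n_channels(img))) {
    ch <- out[i, , ]
    pos <- as.vector(ch)
    pos <- pos[pos > 0]
    hi <- if (length(pos)) percentile(pos, clip_percentile) else 0
    ch <- pmin(pmax(ch, 0), hi)
    ch <- gaussian_blur(ch, sigma)
    out[i, , ] <- zscore_channel(ch, img$channel_names[i])
  }
  multichannel_image(out, img$channel_names, "clip_blur_z")
}

#' @rdname normalization
#' @export
normalize_z <- function(img) {
  check_unnormalized(img)
  out <- img$pixels
  for (i in seq_len(n_channels(img))) {
    out[i, , ] <- zscore_channel(out[i, , ], img$channel_names[i])
  }
  multichannel_image(out, img$channel_names, "z")
}

#' @rdname normalization
#' @param recipe One of `"arcsinh_z"`, `"clip_blur_z"`, `"z"`, `"none"`.
#' @param ... Passed to the chosen recipe.
#' @export
normalize_image <- function(img, recipe, ...) {
  switch(recipe,
    arcsinh_z = normalize_arcsinh_z(img, ...),
    clip_blur_z = normalize_clip_blur_z(img, ...),
    z = normalize_z(img),
    none = img,
    abort(sprintf("unknown normalization recipe: %s", recipe))
  )
}

# Separable Gaussian blur with reflective boundary handling. The kernel is a
# discretized Gaussian truncated at ceiling(4*sigma) taps each side and
# renormalized to sum 1.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- as.integer(ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  # mirror index (edge pixel not duplicated) folded into 1..n, period 2n-2
  reflect <- function(i, n) {
    if (n == 1L) return(rep(1L, length(i)))
    p <- (i - 1L) %% (2L * n - 2L)
    ifelse(p < n, p + 1L, 2L * n - 1L - p)
  }
  blur_1d <- function(m) {
    n <- nrow(m)
    idx <- reflect(seq.int(1L - r, n + r), n)
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(mat))))
}
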