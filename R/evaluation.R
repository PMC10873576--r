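#' Pixel-level reconstruction error
#'
#' Mean squared error between a predicted and a real image, per channel and
#' averaged over channels. Channels are matched by name; a shape or name
#' mismatch is an error.
#'
#' @param pred,real `multichannel_image`s with identical shapes and channel
#'   names (order may differ; `pred` is reordered to match `real`).
#' @return A list with `per_channel` (tibble: `marker`, `mse`) and `overall`
#'   (mean over channels).
#' @export
image_mse <- function(pred, real) {
  check_comparable(pred, real)
  pred <- subset_channels(pred, channel_names(real))
  mse <- vapply(seq_len(n_channels(real)), function(i) {
    mean((pred$pixels[i, , ] - real$pixels[i, , ])^2)
  }, numeric(1))
  list(
    per_channel = tibble(marker = channel_names(real), mse = mse),
    overall = mean(mse)
  )
}

#' Pixel-wise Pearson correlation per channel
#'
#' @inheritParams image_mse
#' @return A tibble with columns `marker`, `pcc`, `defined`; a constant
#'   channel (in either image) yields `defined = FALSE` and `pcc = NA`
#'   rather than propagating NaN.
#' @export
image_pcc <- function(pred, real) {
  check_comparable(pred, real)
  pred <- subset_channels(pred, channel_names(real))
  rows <- lapply(seq_len(n_channels(real)), function(i) {
    a <- as.vector(pred$pixels[i, , ])
    b <- as.vector(real$pixels[i, , ])
    if (sd_pop(a) < 1e-12 || sd_pop(b) < 1e-12) {
      tibble(marker = channel_names(real)[i], pcc = NA_real_,
             defined = FALSE)
    } else {
      tibble(marker = channel_names(real)[i],
             pcc = stats::cor(a, b), defined = TRUE)
    }
  })
  bind_rows(rows)
}

check_comparable <- function(pred, real) {
  if (!setequal(channel_names(pred), channel_names(real))) {
    abort("images have different channel names")
  }
  if (!all(image_dim(pred) == image_dim(real))) {
    abort("images have different pixel dimensions")
  }
}

#' Single-cell mean-intensity profile
#'
#' A cells x markers matrix: each entry is the mean intensity of one marker
#' over one segmented cell's pixels (background, label 0, is excluded).
#'
#' @param img A `multichannel_image`.
#' @param mask A `cell_mask` of the same spatial shape.
#' @return A `single_cell_profile` whose `$means` is the cells x markers
#'   matrix (rownames = cell labels); see also [profile_to_tibble()].
#' @export
cell_mean_profile <- function(img, mask) {
  check_mask(img, mask)
  labs <- sort(setdiff(unique(as.vector(mask$labels)), 0L))
  if (!length(labs)) abort("mask contains no cells")
  m <- matrix(NA_real_, length(labs), n_channels(img),
              dimnames = list(labs, channel_names(img)))
  lab_vec <- as.vector(mask$labels)
  for (i in seq_len(n_channels(img))) {
    ch <- as.vector(img$pixels[i, , ])
    agg <- vapply(split(ch, lab_vec), mean, numeric(1))
    m[, i] <- agg[as.character(labs)]
  }
  new_profile(means = m)
}

#' Single-cell correlation profile
#'
#' A cells x marker-pairs matrix: each entry is the Pearson correlation
#' between two markers' intensities over one cell's pixels. Pair columns are
#' ordered lexicographically by `(i, j)`, `i < j`, in channel order. Cells
#' with fewer than 2 pixels, or a constant channel within the cell, get NA
#' (flagged undefined) for the affected pairs.
#'
#' @inheritParams cell_mean_profile
#' @return A `single_cell_profile` whose `$correlations` is the cells x
#'   pairs matrix (colnames `"A|B"`).
#' @export
cell_correlation_profile <- function(img, mask) {
  check_mask(img, mask)
  labs <- sort(setdiff(unique(as.vector(mask$labels)), 0L))
  if (!length(labs)) abort("mask contains no cells")
  nm <- channel_names(img)
  n <- length(nm)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  pair_names <- paste(nm[pairs[, 1]], nm[pairs[, 2]], sep = "|")
  lab_vec <- as.vector(mask$labels)
  chans <- lapply(seq_len(n), function(i) as.vector(img$pixels[i, , ]))
  cmat <- matrix(NA_real_, length(labs), nrow(pairs),
                 dimnames = list(labs, pair_names))
  for (ci in seq_along(labs)) {
    sel <- lab_vec == labs[ci]
    if (sum(sel) < 2) next
    for (pi in seq_len(nrow(pairs))) {
      a <- chans[[pairs[pi, 1]]][sel]
      b <- chans[[pairs[pi, 2]]][sel]
      if (sd_pop(a) < 1e-12 || sd_pop(b) < 1e-12) next
      cmat[ci, pi] <- stats::cor(a, b)
    }
  }
  new_profile(correlations = cmat)
}

new_profile <- function(means = NULL, correlations = NULL) {
  structure(list(means = means, correlations = correlations),
            class = "single_cell_profile")
}

#' @export
print.single_cell_profile <- function(x, ...) {
  parts <- c(
    if (!is.null(x$means)) sprintf("means %d x %d", nrow(x$means),
                                   ncol(x$means)),
    if (!is.null(x$correlations)) sprintf("correlations %d x %d",
                                          nrow(x$correlations),
                                          ncol(x$correlations))
  )
  cat("<single_cell_profile>", paste(parts, collapse = "; "), "\n")
  invisible(x)
}

check_mask <- function(img, mask) {
  if (!inherits(mask, "cell_mask")) abort("mask must be a cell_mask")
  if (!all(dim(mask$labels) == image_dim(img))) {
    abort("mask shape does not match the image")
  }
}

profile_matrix <- function(p) {
  if (!is.null(p$means) && !is.null(p$correlations)) {
    cbind(p$means, p$correlations)
  } else {
    p$means %||% p$correlations
  }
}

#' Distance between two single-cell profiles
#'
#' The normalized Frobenius norm of the entrywise difference. The default
#' normalization is the root mean square of the compared entries
#' (`||A - B||_F / sqrt(#entries)`); `method = "relative"` instead divides
#' by `||B||_F`. Entries undefined (NA) in either profile are excluded
#' pairwise rather than zero-filled — zero-filling would fabricate signal in
#' tiny cells.
#'
#' @param a,b `single_cell_profile`s with matching shape and labels.
#' @param method `"rms"` (default) or `"relative"`.
#' @return A nonnegative scalar.
#' @export
profile_distance <- function(a, b, method = c("rms", "relative")) {
  method <- match.arg(method)
  ma <- profile_matrix(a)
  mb <- profile_matrix(b)
  if (is.null(ma) || is.null(mb) || !all(dim(ma) == dim(mb))) {
    abort("profiles have different shapes")
  }
  if (!identical(rownames(ma), rownames(mb)) ||
      !identical(colnames(ma), colnames(mb))) {
    abort("profiles have different cell or column labels")
  }
  ok <- !is.na(ma) & !is.na(mb)
  if (!any(ok)) abort("no comparable entries between the profiles")
  d <- ma[ok] - mb[ok]
  switch(method,
    rms = sqrt(sum(d^2) / sum(ok)),
    relative = sqrt(sum(d^2)) / sqrt(sum(mb[ok]^2))
  )
}

#' Single-cell profile as a tibble
#'
#' @param profile A `single_cell_profile`.
#' @return A tibble with a `cell` column followed by marker or pair columns.
#' @export
profile_to_tibble <- function(profile) {
  m <- profile_matrix(profile)
  dplyr::bind_cols(tibble(cell = as.integer(rownames(m))), as_tibble(m))
}

#' Write a profile as CSV
#'
#' @param profile A `single_cell_profile`.
#' @param path Output path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile_to_tibble(profile), path, row.names = FALSE)
  invisible(path)
}

#' Read a profile written by [write_profile_csv()]
#'
#' Columns containing `|` are interpreted as marker-pair correlations.
#'
#' @param path CSV path.
#' @return A `single_cell_profile`.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cells <- df$cell
  rest <- as.matrix(df[, setdiff(names(df), "cell"), drop = FALSE])
  rownames(rest) <- cells
  is_pair <- grepl("|", colnames(rest), fixed = TRUE)
  new_profile(
    means = if (any(!is_pair)) rest[, !is_pair, drop = FALSE],
    correlations = if (any(is_pair)) rest[, is_pair, drop = FALSE]
  )
}

#' Evaluate a fitted selection on the test split
#'
#' Predicts every unobserved marker of each test image with the final model
#' (or panel models for a `multipanel_result`), and reports per-marker MSE
#' and Pearson correlation pooled over test images, plus the overall MSE
#' (mean over predicted markers).
#'
#' @param result A `selection_result` or `multipanel_result`.
#' @param test Optional list of test `multichannel_image`s containing all
#'   channels; defaults to the result's dataset test split (single-panel
#'   only).
#' @return A list with `per_marker` (tibble: `marker`, `mse`, `pcc`) and
#'   `overall_mse`.
#' @export
evaluate_selection <- function(result, test = NULL) {
  if (is.null(test)) {
    if (inherits(result, "multipanel_result")) {
      abort("multipanel results need an explicit full-channel test set")
    }
    test <- result$dataset$test
  }
  if (!length(test)) abort("no test images")
  pred_markers <- setdiff(result$graph$markers, result$observed)
  if (!length(pred_markers)) {
    return(list(per_marker = tibble(marker = character(), mse = numeric(),
                                    pcc = numeric()),
                overall_mse = 0))
  }
  se <- stats::setNames(numeric(length(pred_markers)), pred_markers)
  npx <- 0
  preds <- list()
  reals <- list()
  for (im in test) {
    p <- if (inherits(result, "multipanel_result")) {
      predict_multipanel(result, im)
    } else {
      predict(result$model, im)
    }
    p <- subset_channels(p, pred_markers)
    r <- subset_channels(im, pred_markers)
    preds[[length(preds) + 1L]] <- p
    reals[[length(reals) + 1L]] <- r
    for (mk in pred_markers) {
      se[mk] <- se[mk] + sum((get_channel(p, mk) - get_channel(r, mk))^2)
    }
    npx <- npx + prod(image_dim(im))
  }
  mse <- se / npx
  pcc <- vapply(pred_markers, function(mk) {
    a <- unlist(lapply(preds, get_channel, channel = mk))
    b <- unlist(lapply(reals, get_channel, channel = mk))
    if (sd_pop(a) < 1e-12 || sd_pop(b) < 1e-12) NA_real_ else stats::cor(a, b)
  }, numeric(1))
  list(
    per_marker = tibble(marker = pred_markers, mse = unname(mse),
                        pcc = unname(pcc)),
    overall_mse = mean(mse)
  )
}
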