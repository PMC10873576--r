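#' Multichannel image dataset with train/validation/test splits
#'
#' Bundles the three image splits used throughout selection: the training set
#' (edge-loading initialization and model fitting), the validation set
#' (model risks that update edge loadings), and a held-out test set
#' (final evaluation only). All images must share an identical ordered
#' channel-name vector.
#'
#' @param train,val,test Lists of `multichannel_image` objects.
#' @return A `multichannel_dataset`.
#' @export
multichannel_dataset <- function(train, val = list(), test = list()) {
  splits <- list(train = train, val = val, test = test)
  imgs <- c(train, val, test)
  if (!length(train)) abort("training split must contain at least one image")
  for (im in imgs) {
    if (!is_multichannel_image(im)) {
      abort("all dataset elements must be multichannel_image objects")
    }
  }
  nm <- channel_names(imgs[[1]])
  for (im in imgs) {
    if (!identical(channel_names(im), nm)) {
      abort("all images in a dataset must share identical channel names")
    }
  }
  structure(c(splits, list(channel_names = nm)),
            class = "multichannel_dataset")
}

#' @export
print.multichannel_dataset <- function(x, ...) {
  cat(sprintf(
    "<multichannel_dataset> %d markers; images: %d train / %d val / %d test\n",
    length(x$channel_names), length(x$train), length(x$val), length(x$test)
  ))
  cat("markers:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname multichannel_dataset
#' @param x An object.
#' @export
is_multichannel_dataset <- function(x) inherits(x, "multichannel_dataset")

#' Apply a normalization recipe to every image of a dataset
#'
#' @param dataset A `multichannel_dataset`.
#' @param recipe Normalization recipe name (see [normalize_image()]).
#' @param ... Passed to the recipe.
#' @return A normalized `multichannel_dataset`.
#' @export
normalize_dataset <- function(dataset, recipe, ...) {
  norm <- function(lst) lapply(lst, normalize_image, recipe = recipe, ...)
  multichannel_dataset(norm(dataset$train), norm(dataset$val),
                       norm(dataset$test))
}

#' Restrict every image of a dataset to a channel subset
#'
#' Used to simulate multi-panel acquisition by channel-masking a full
#' dataset: each panel sees only its own markers.
#'
#' @param dataset A `multichannel_dataset`.
#' @param channels Character vector of channel names to keep.
#' @return A `multichannel_dataset` over the requested channels.
#' @export
subset_dataset <- function(dataset, channels) {
  sub <- function(lst) lapply(lst, subset_channels, channels = channels)
  multichannel_dataset(sub(dataset$train), sub(dataset$val),
                       sub(dataset$test))
}

dataset_normalized <- function(dataset) {
  flags <- vapply(c(dataset$train, dataset$val, dataset$test),
                  function(im) im$normalized, character(1))
  all(flags != "none")
}
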