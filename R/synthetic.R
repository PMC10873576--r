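#' Synthetic multichannel imaging configuration
#'
#' The generator emulates the statistical structure the selection method
#' exploits in real multiplexed images: a small number `K` of latent spatial
#' factors (blobby, cell-anchored fields) mixed into `N` observed marker
#' channels through a known `N x K` mixing matrix, plus independent channel
#' noise. Cell centers are placed uniformly; each latent field is a sum of
#' truncated-Gaussian radial kernels around the centers with cell-specific
#' latent weights, giving spatially structured, inter-correlated channels.
#' Within each image the latent fields are centered and whitened (identity
#' population covariance), so every channel's per-image z-score is an
#' image-independent linear map of the latents: with `noise_sd = 0` and
#' `nonlinearity = "none"` each channel is an *exact* linear combination of
#' the `K` anchor channels, which is what makes exact-recovery tests
#' possible.
#'
#' Mixing rows are normalized to unit L2 norm so that, after per-channel
#' z-scoring, the noise floor of every channel is `noise_sd^2 /
#' (1 + noise_sd^2)` in variance terms.
#'
#' Three independent seed streams (mixing, fields, noise) let experiments
#' vary one factor at a time; splits draw from disjoint substreams.
#'
#' @param n_markers Number of marker channels `N`.
#' @param n_latents Number of latent factors `K` (`K <= N`).
#' @param height,width Image size in pixels.
#' @param n_train,n_val,n_test Images per split.
#' @param n_cells Cell centers per image.
#' @param noise_sd Channel noise SD, in units of the (unit-variance) clean
#'   channel signal.
#' @param nonlinearity `"none"` or `"softplus"` applied to the mixed signal.
#' @param mixing_seed,field_seed,noise_seed Integer seeds.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_markers = 12L, n_latents = 3L,
                             height = 64L, width = 64L,
                             n_train = 4L, n_val = 2L, n_test = 2L,
                             n_cells = 25L, noise_sd = 0,
                             nonlinearity = c("none", "softplus"),
                             mixing_seed = 11L, field_seed = 12L,
                             noise_seed = 13L) {
  nonlinearity <- match.arg(nonlinearity)
  if (n_latents > n_markers) abort("n_latents must not exceed n_markers")
  if (noise_sd < 0) abort("noise_sd must be nonnegative")
  if (n_cells < n_latents) abort("n_cells must be at least n_latents")
  structure(
    list(n_markers = as.integer(n_markers), n_latents = as.integer(n_latents),
         height = as.integer(height), width = as.integer(width),
         n_train = as.integer(n_train), n_val = as.integer(n_val),
         n_test = as.integer(n_test), n_cells = as.integer(n_cells),
         noise_sd = noise_sd, nonlinearity = nonlinearity,
         mixing_seed = as.integer(mixing_seed),
         field_seed = as.integer(field_seed),
         noise_seed = as.integer(noise_seed)),
    class = "synthetic_config"
  )
}

marker_ids <- function(n) sprintf("M%02d", seq_len(n))

# Mixing matrix with unit-norm rows whose K x K anchor block (first K rows)
# is well conditioned; regenerated (bounded retries) if nearly singular.
generate_mixing <- function(config) {
  K <- config$n_latents
  N <- config$n_markers
  for (try in 1:100) {
    a <- with_rng(derive_seed(config$mixing_seed, try), {
      matrix(stats::rnorm(N * K), N, K)
    })
    a <- a / sqrt(rowSums(a^2))
    if (K == 1) break
    if (kappa(a[seq_len(K), , drop = FALSE]) < 50) break
  }
  rownames(a) <- marker_ids(N)
  a
}

# Per-image geometry and latent fields. Returns whitened latent fields
# (npix x K, exactly zero mean and identity population covariance), plus the
# cell centers/radii/weights that produced them.
generate_latents <- function(config, img_seed) {
  h <- config$height
  w <- config$width
  K <- config$n_latents
  nc <- config$n_cells
  geom <- with_rng(img_seed, {
    list(
      centers = cbind(row = stats::runif(nc, 1, h),
                      col = stats::runif(nc, 1, w)),
      radii = 0.6 * sqrt(h * w / nc) * stats::runif(nc, 0.8, 1.2),
      weights = matrix(stats::rnorm(nc * K), nc, K)
    )
  })
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  fields <- matrix(0, h * w, K)
  for (c_i in seq_len(nc)) {
    d2 <- (rows - geom$centers[c_i, 1])^2 + (cols - geom$centers[c_i, 2])^2
    r <- geom$radii[c_i]
    kern <- exp(-d2 / (2 * r^2)) * (d2 < (3 * r)^2)
    fields <- fields + as.vector(kern) %o% geom$weights[c_i, ]
  }
  # center and whiten: population covariance becomes exactly I_K
  fields <- sweep(fields, 2, colMeans(fields))
  cv <- crossprod(fields) / nrow(fields)
  ch <- tryCatch(chol(cv), error = function(e) {
    chol(cv + diag(1e-10, K))
  })
  fields <- fields %*% solve(ch)
  list(fields = fields, geom = geom)
}

#' Generate a synthetic multichannel dataset with known ground truth
#'
#' @param config A [synthetic_config()].
#' @return A list with `dataset` (a normalized `multichannel_dataset`, flag
#'   `"z"`), and `truth` (`synthetic_truth`: mixing matrix, anchor marker
#'   set, per-image latent fields / cell geometry keyed by split, and cell
#'   masks from [generate_cell_masks()]).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("config must be a synthetic_config")
  }
  mixing <- generate_mixing(config)
  ids <- marker_ids(config$n_markers)
  splits <- list(train = config$n_train, val = config$n_val,
                 test = config$n_test)
  images <- list()
  latents <- list()
  geoms <- list()
  for (s in seq_along(splits)) {
    split_name <- names(splits)[s]
    images[[split_name]] <- vector("list", splits[[s]])
    latents[[split_name]] <- vector("list", splits[[s]])
    geoms[[split_name]] <- vector("list", splits[[s]])
    for (i in seq_len(splits[[s]])) {
      lat <- generate_latents(config, derive_seed(config$field_seed, s, i))
      signal <- lat$fields %*% t(mixing) # npix x N
      if (config$nonlinearity == "softplus") {
        signal <- log1p(exp(signal))
      }
      if (config$noise_sd > 0) {
        eps <- with_rng(derive_seed(config$noise_seed, s, i), {
          matrix(stats::rnorm(length(signal), sd = config$noise_sd),
                 nrow(signal), ncol(signal))
        })
        signal <- signal + eps
      }
      pix <- array(0, c(config$n_markers, config$height, config$width))
      for (m in seq_len(config$n_markers)) {
        ch <- matrix(signal[, m], config$height, config$width)
        s_ch <- sd_pop(ch)
        pix[m, , ] <- if (s_ch < 1e-12) 0 else (ch - mean(ch)) / s_ch
      }
      images[[split_name]][[i]] <- multichannel_image(pix, ids, "z")
      latents[[split_name]][[i]] <- lat$fields
      geoms[[split_name]][[i]] <- lat$geom
    }
  }
  truth <- structure(
    list(
      mixing = mixing,
      anchors = ids[seq_len(config$n_latents)],
      latents = latents,
      geometry = geoms,
      config = config
    ),
    class = "synthetic_truth"
  )
  truth$masks <- generate_cell_masks(config)
  list(
    dataset = multichannel_dataset(images$train, images$val, images$test),
    truth = truth
  )
}

#' Generate cell label masks aligned with the synthetic images
#'
#' Labels each pixel with the nearest cell center if it lies within that
#' cell's disc radius, 0 (background) otherwise. Deterministic: uses the
#' same derived per-image seeds as [generate_dataset()], so masks align with
#' the generated fields.
#'
#' @param config A [synthetic_config()].
#' @return A list of lists of `cell_mask` keyed by split
#'   (`train`/`val`/`test`).
#' @export
generate_cell_masks <- function(config) {
  splits <- list(train = config$n_train, val = config$n_val,
                 test = config$n_test)
  h <- config$height
  w <- config$width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  out <- list()
  for (s in seq_along(splits)) {
    split_name <- names(splits)[s]
    out[[split_name]] <- vector("list", splits[[s]])
    for (i in seq_len(splits[[s]])) {
      geom <- generate_latents(config, derive_seed(config$field_seed, s, i))$geom
      best_d2 <- matrix(Inf, h, w)
      lab <- matrix(0L, h, w)
      for (c_i in seq_len(config$n_cells)) {
        d2 <- (rows - geom$centers[c_i, 1])^2 + (cols - geom$centers[c_i, 2])^2
        hit <- d2 < best_d2 & d2 < geom$radii[c_i]^2
        lab[hit] <- c_i
        best_d2[hit] <- d2[hit]
      }
      out[[split_name]][[i]] <- cell_mask(lab)
    }
  }
  out
}

#' Ground-truth-correlated marker feature vectors
#'
#' Emits one feature vector per marker: its mixing-matrix row plus Gaussian
#' perturbation. Markers with similar mixing (hence similar channels) get
#' similar features — a stand-in for embedding-derived marker features used
#' to design panels.
#'
#' @param truth A `synthetic_truth` from [generate_dataset()].
#' @param noise Perturbation SD.
#' @param seed Integer seed.
#' @return A tibble with column `marker` and feature columns `f1..fK`.
#' @export
generate_marker_features <- function(truth, noise = 0, seed = 1L) {
  a <- truth$mixing
  pert <- with_rng(seed, {
    matrix(stats::rnorm(length(a), sd = noise), nrow(a), ncol(a))
  })
  f <- a + pert
  colnames(f) <- paste0("f", seq_len(ncol(f)))
  dplyr::bind_cols(tibble(marker = rownames(a)), as_tibble(f))
}

#' Irreducible prediction risk of the generator, given an observed set
#'
#' The population-optimal linear predictor's mean squared error for each
#' unobserved marker, computed in closed form from the generator's ground
#' truth (mixing matrix and noise level) rather than from any fitted model.
#' Within each image the latent fields are whitened, so z-scored channels
#' have `Var(z_i) = 1` and `Cov(z_i, z_j) = a_i . a_j / (1 + sigma^2)`; the
#' optimal risk for target `j` given observed set `O` is
#' `1 - c' Sigma_OO^{-1} c` with `c = A_O a_j / (1 + sigma^2)` and
#' `Sigma_OO = (A_O A_O' + sigma^2 I) / (1 + sigma^2)`. This is the noise
#' floor a fitted predictor is compared against: it accounts for noise on
#' the *observed* channels as well as on the target.
#'
#' @param truth A `synthetic_truth`.
#' @param observed Character vector of observed markers.
#' @return A list with `per_marker` (named vector over unobserved markers)
#'   and `overall` (their mean).
#' @export
synthetic_noise_floor <- function(truth, observed) {
  a <- truth$mixing
  s2 <- truth$config$noise_sd^2
  pred <- setdiff(rownames(a), observed)
  if (!length(pred)) return(list(per_marker = numeric(), overall = 0))
  ao <- a[observed, , drop = FALSE]
  soo <- (ao %*% t(ao) + s2 * diag(length(observed))) / (1 + s2)
  per <- vapply(pred, function(j) {
    cv <- ao %*% a[j, ] / (1 + s2)
    max(0, 1 - as.numeric(t(cv) %*% solve(soo, cv)))
  }, numeric(1))
  list(per_marker = per, overall = mean(per))
}

#' Write a synthetic study to disk
#'
#' Writes per-split images (multi-page TIFF + channel-name sidecars), label
#' masks, and a `truth.json` with the mixing matrix, anchors and seeds, so a
#' full synthetic study is a self-contained directory.
#'
#' @param generated The list returned by [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generated$dataset
  truth <- generated$truth
  for (split in c("train", "val", "test")) {
    for (i in seq_along(ds[[split]])) {
      write_multichannel(ds[[split]][[i]],
                         file.path(dir, sprintf("%s_%02d.tif", split, i)))
      write_cell_mask(truth$masks[[split]][[i]],
                      file.path(dir, sprintf("%s_%02d_mask.tif", split, i)))
    }
  }
  jsonlite::write_json(
    list(
      mixing = unname(lapply(seq_len(nrow(truth$mixing)),
                             function(i) truth$mixing[i, ])),
      markers = rownames(truth$mixing),
      anchors = truth$anchors,
      config = unclass(truth$config)
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
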