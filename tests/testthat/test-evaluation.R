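two_channel_image <- function(a, b, names = c("A", "B"), normalized = "z") {
  px <- array(0, c(2, nrow(a), ncol(a)))
  px[1, , ] <- a
  px[2, , ] <- b
  multichannel_image(px, names, normalized)
}

test_that("image MSE matches direct elementwise computation", {
  set.seed(51)
  a <- matrix(rnorm(36), 6, 6)
  b <- matrix(rnorm(36), 6, 6)
  real <- two_channel_image(a, b)
  expect_equal(image_mse(real, real)$overall, 0)
  off <- two_channel_image(a + 0.5, b + 0.5)
  expect_equal(image_mse(off, real)$overall, 0.25)
  set.seed(52)
  pred <- two_channel_image(matrix(rnorm(36), 6, 6), matrix(rnorm(36), 6, 6))
  out <- image_mse(pred, real)
  expect_equal(out$per_channel$mse[1],
               mean((pred$pixels[1, , ] - a)^2))
  expect_equal(out$overall, mean(out$per_channel$mse))
  # channels are matched by name, not position
  swapped <- subset_channels(pred, c("B", "A"))
  expect_equal(image_mse(swapped, real)$overall, out$overall)
  bad <- two_channel_image(a, b, names = c("A", "C"))
  expect_error(image_mse(bad, real), "different channel names")
})

test_that("pixelwise PCC matches the textbook formula and flags constants", {
  set.seed(53)
  a <- matrix(rnorm(64), 8, 8)
  b <- matrix(rnorm(64), 8, 8)
  real <- two_channel_image(a, b)
  expect_equal(image_pcc(real, real)$pcc, c(1, 1))
  neg <- two_channel_image(-a, -b)
  expect_equal(image_pcc(neg, real)$pcc, c(-1, -1))
  set.seed(54)
  pred <- two_channel_image(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8))
  got <- image_pcc(pred, real)$pcc[1]
  x <- as.vector(pred$pixels[1, , ])
  y <- as.vector(a)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got, manual)
  # affine rescaling leaves |pcc| unchanged
  scaled <- two_channel_image(3 * pred$pixels[1, , ] + 1,
                              -2 * pred$pixels[2, , ] + 5)
  out <- image_pcc(scaled, real)
  expect_equal(out$pcc[1], image_pcc(pred, real)$pcc[1], tolerance = 1e-12)
  expect_equal(out$pcc[2], -image_pcc(pred, real)$pcc[2], tolerance = 1e-12)
  # constant channel: undefined flag, not NaN
  const <- two_channel_image(matrix(1, 8, 8), b)
  flags <- image_pcc(const, real)
  expect_false(flags$defined[1])
  expect_true(is.na(flags$pcc[1]))
  expect_true(flags$defined[2])
})

test_that("cell mean profiles average each cell's pixels per marker", {
  ch <- matrix(c(1, 3, 2, 4), 2, 2) # column-major: [1,3;2,4] -> values 1..4
  img <- two_channel_image(ch, 10 * ch)
  mask <- cell_mask(matrix(1L, 2, 2))
  prof <- cell_mean_profile(img, mask)
  expect_equal(unname(prof$means[1, ]), c(2.5, 25))
  # two disjoint cells + excluded background
  mask2 <- cell_mask(matrix(c(1L, 0L, 2L, 2L), 2, 2))
  prof2 <- cell_mean_profile(img, mask2)
  expect_equal(rownames(prof2$means), c("1", "2"))
  expect_equal(unname(prof2$means["1", "A"]), 1)
  expect_equal(unname(prof2$means["2", "A"]), mean(c(2, 4)))
  expect_error(cell_mean_profile(img, cell_mask(matrix(0L, 2, 2))),
               "no cells")
  # oracle on a random image/mask
  set.seed(55)
  big <- two_channel_image(matrix(rnorm(48), 6, 8), matrix(rnorm(48), 6, 8))
  labs <- matrix(sample(0:3, 48, replace = TRUE), 6, 8)
  p <- cell_mean_profile(big, cell_mask(labs))
  for (k in 1:3) {
    expect_equal(unname(p$means[as.character(k), "B"]),
                 mean(big$pixels[2, , ][labs == k]))
  }
})

test_that("cell correlation profiles detect within-cell linear relations", {
  set.seed(56)
  a <- matrix(rnorm(36), 6, 6)
  img <- two_channel_image(a, 2 * a) # B = 2A exactly
  mask <- cell_mask(matrix(rep(1:2, each = 18), 6, 6))
  prof <- cell_correlation_profile(img, mask)
  expect_equal(colnames(prof$correlations), "A|B")
  expect_equal(unname(prof$correlations[, 1]), c(1, 1), tolerance = 1e-12)
  # single-pixel cell: undefined
  labs <- matrix(0L, 6, 6)
  labs[1, 1] <- 1L
  labs[, 4:6] <- 2L
  p2 <- cell_correlation_profile(img, cell_mask(labs))
  expect_true(is.na(p2$correlations["1", 1]))
  expect_false(is.na(p2$correlations["2", 1]))
  # random case matches direct computation
  set.seed(57)
  img3 <- two_channel_image(matrix(rnorm(36), 6, 6), matrix(rnorm(36), 6, 6))
  p3 <- cell_correlation_profile(img3, mask)
  sel <- rep(1:2, each = 18) == 1
  expect_equal(unname(p3$correlations["1", 1]),
               cor(as.vector(img3$pixels[1, , ])[sel],
                   as.vector(img3$pixels[2, , ])[sel]))
})

test_that("profile distance is the entrywise RMS and behaves like a metric", {
  set.seed(58)
  mk_prof <- function(m) {
    dimnames(m) <- list(1:4, c("A", "B", "C"))
    panelpick:::new_profile(means = m)
  }
  a <- mk_prof(matrix(rnorm(12), 4, 3))
  expect_equal(profile_distance(a, a), 0)
  shifted <- mk_prof(a$means + 0.1)
  expect_equal(profile_distance(a, shifted), 0.1, tolerance = 1e-12)
  b <- mk_prof(matrix(rnorm(12), 4, 3))
  expect_equal(profile_distance(a, b),
               sqrt(mean((a$means - b$means)^2)))
  # relative normalization variant
  expect_equal(profile_distance(a, b, method = "relative"),
               sqrt(sum((a$means - b$means)^2)) / sqrt(sum(b$means^2)))
  # metric properties on random triples
  for (i in 1:5) {
    x <- mk_prof(matrix(rnorm(12), 4, 3))
    y <- mk_prof(matrix(rnorm(12), 4, 3))
    z <- mk_prof(matrix(rnorm(12), 4, 3))
    expect_equal(profile_distance(x, y), profile_distance(y, x))
    expect_lte(profile_distance(x, z),
               profile_distance(x, y) + profile_distance(y, z) + 1e-12)
  }
  # NA entries are excluded pairwise
  a2 <- a
  a2$means[1, 1] <- NA
  d <- profile_distance(a2, b)
  ok <- !is.na(a2$means)
  expect_equal(d, sqrt(mean((a2$means[ok] - b$means[ok])^2)))
})

test_that("profiles survive a CSV round trip", {
  set.seed(59)
  img <- two_channel_image(matrix(rnorm(36), 6, 6), matrix(rnorm(36), 6, 6))
  mask <- cell_mask(matrix(rep(1:3, each = 12), 6, 6))
  means <- cell_mean_profile(img, mask)
  corrs <- cell_correlation_profile(img, mask)
  both <- panelpick:::new_profile(means = means$means,
                                  correlations = corrs$correlations)
  path <- file.path(withr::local_tempdir(), "profile.csv")
  write_profile_csv(both, path)
  back <- read_profile_csv(path)
  expect_equal(back$means, both$means, tolerance = 1e-12)
  expect_equal(back$correlations, both$correlations, tolerance = 1e-12)
  expect_equal(profile_distance(back, both), 0, tolerance = 1e-9)
})

test_that("all measures are covariant under channel relabeling", {
  set.seed(60)
  a <- matrix(rnorm(36), 6, 6)
  b <- matrix(rnorm(36), 6, 6)
  real <- two_channel_image(a, b)
  pred <- two_channel_image(a + rnorm(36, sd = 0.1), b + rnorm(36, sd = 0.1))
  # relabel both inputs identically (swap channel order)
  real_r <- subset_channels(real, c("B", "A"))
  pred_r <- subset_channels(pred, c("B", "A"))
  expect_equal(image_mse(pred_r, real_r)$overall,
               image_mse(pred, real)$overall)
  expect_setequal(image_pcc(pred_r, real_r)$pcc, image_pcc(pred, real)$pcc)
  mask <- cell_mask(matrix(rep(1:2, each = 18), 6, 6))
  p1 <- cell_mean_profile(real, mask)
  p2 <- cell_mean_profile(real_r, mask)
  expect_equal(p2$means[, c("A", "B")], p1$means)
})
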