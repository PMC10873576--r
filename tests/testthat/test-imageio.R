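test_that("multichannel images validate their structure", {
  px <- array(1, c(3, 4, 5))
  img <- multichannel_image(px, c("A", "B", "C"))
  expect_equal(channel_names(img), c("A", "B", "C"))
  expect_equal(image_dim(img), c(4, 5))
  expect_error(multichannel_image(px, c("A", "B")), "does not match")
  expect_error(multichannel_image(px, c("A", "A", "B")), "unique")
})

test_that("TIFF write/read round trip is bit-exact at float32 precision", {
  img <- rand_image(3, 6, 7, seed = 2, names = c("A", "B", "C"))
  # float32-representable pixels so the round trip is exactly identical
  img$pixels[] <- panelpick:::as_float32(img$pixels)
  path <- file.path(withr::local_tempdir(), "img.tif")
  write_multichannel(img, path)
  back <- read_multichannel(path)
  expect_identical(back$pixels, img$pixels)
  expect_identical(channel_names(back), channel_names(img))
  expect_equal(back$normalized, "none")
  # explicit names override the sidecar
  back2 <- read_multichannel(path, names = c("X", "Y", "Z"))
  expect_identical(channel_names(back2), c("X", "Y", "Z"))
  # name-count mismatch
  expect_error(read_multichannel(path, names = c("X", "Y")), "does not match")
  expect_error(read_multichannel(file.path(tempdir(), "absent.tif")),
               "not found")
})

test_that("degenerate 1x1x1 image survives a write/read cycle", {
  img <- multichannel_image(array(0.5, c(1, 1, 1)), "solo")
  path <- file.path(withr::local_tempdir(), "one.tif")
  write_multichannel(img, path)
  expect_equal(read_multichannel(path)$pixels, img$pixels)
})

test_that("cell masks round-trip through label TIFFs", {
  lab <- matrix(sample(0:4, 30, replace = TRUE), 5, 6)
  mask <- cell_mask(lab)
  path <- file.path(withr::local_tempdir(), "mask.tif")
  write_cell_mask(mask, path)
  expect_identical(read_cell_mask(path)$labels, mask$labels)
  expect_error(cell_mask(matrix(-1, 2, 2)), "nonnegative")
})

test_that("arcsinh recipe uses the max(5*q20, 15) divisor and z-scores", {
  set.seed(3)
  # channel built so its 20th percentile is exactly 2 -> divisor 15
  v <- as.numeric(quantile(0:100, probs = seq(0, 1, length.out = 64)))
  ch <- matrix(2 * v / as.numeric(quantile(v, 0.2)), 8, 8)
  expect_equal(as.numeric(quantile(ch, 0.2)), 2)
  img <- multichannel_image(array(ch, c(1, 8, 8)), "A")
  out <- normalize_arcsinh_z(img)
  expect_equal(out$normalized, "arcsinh_z")
  expect_equal(as.vector(out$pixels[1, , ]), as.vector(zpop(asinh(ch / 15))),
               tolerance = 1e-12)
  # large-intensity channel: q20 big enough that 5*q20 wins
  ch2 <- matrix(seq(10, 600, length.out = 64), 8, 8)
  div2 <- max(5 * as.numeric(quantile(ch2, 0.2)), 15)
  out2 <- normalize_arcsinh_z(multichannel_image(array(ch2, c(1, 8, 8)), "A"))
  expect_gt(div2, 15)
  expect_equal(as.vector(out2$pixels[1, , ]), as.vector(zpop(asinh(ch2 / div2))),
               tolerance = 1e-12)
})

test_that("all three recipes produce mean 0 / SD 1 channels", {
  img <- rand_image(4, 12, 12, seed = 4)
  img$pixels <- abs(img$pixels) # intensities
  for (recipe in c("arcsinh_z", "clip_blur_z", "z")) {
    out <- normalize_image(img, recipe)
    for (i in 1:4) {
      ch <- out$pixels[i, , ]
      expect_lt(abs(mean(ch)), 1e-6)
      expect_lt(abs(sqrt(mean((ch - mean(ch))^2)) - 1), 1e-6)
    }
  }
})

test_that("sigma guard zeroes constant channels with a warning", {
  img <- multichannel_image(array(7, c(1, 4, 4)), "flat")
  expect_warning(out <- normalize_arcsinh_z(img), "sigma guard")
  expect_true(all(out$pixels == 0))
  expect_warning(outz <- normalize_z(img), "sigma guard")
  expect_true(all(outz$pixels == 0))
  # all-zero channel under the IMC recipe: clip bound 0, guard fires
  img0 <- multichannel_image(array(0, c(1, 6, 6)), "zero")
  expect_warning(outc <- normalize_clip_blur_z(img0), "sigma guard")
  expect_true(all(outc$pixels == 0))
})

test_that("z-score recipe is idempotent up to numerical precision", {
  img <- rand_image(2, 10, 10, seed = 5)
  once <- normalize_z(img)
  relabel <- multichannel_image(once$pixels, channel_names(once), "none")
  twice <- normalize_z(relabel)
  expect_equal(twice$pixels, once$pixels, tolerance = 1e-9)
})

test_that("clip/blur recipe matches a brute-force convolution oracle", {
  # impulse image: blurred output is the discretized Gaussian
  ch <- matrix(0, 9, 9)
  ch[5, 5] <- 10
  img <- multichannel_image(array(ch, c(1, 9, 9)), "imp")
  out <- normalize_clip_blur_z(img, sigma = 1.5)
  clipped <- pmin(pmax(ch, 0), as.numeric(quantile(10, 0.98)))
  expect_equal(as.vector(out$pixels[1, , ]),
               as.vector(zpop(conv_blur_oracle(clipped, 1.5))), tolerance = 1e-10)
  # and on a generic random channel (checks separability + reflection)
  set.seed(6)
  ch2 <- matrix(abs(rnorm(8 * 11)), 8, 11)
  img2 <- multichannel_image(array(ch2, c(1, 8, 11)), "rnd")
  out2 <- normalize_clip_blur_z(img2, sigma = 1.5)
  pos <- ch2[ch2 > 0]
  clipped2 <- pmin(pmax(ch2, 0), as.numeric(quantile(pos, 0.98)))
  expect_equal(as.vector(out2$pixels[1, , ]),
               as.vector(zpop(conv_blur_oracle(clipped2, 1.5))), tolerance = 1e-10)
})

test_that("random patches are reproducible and correctly shaped", {
  img <- rand_image(3, 20, 20, seed = 7)
  p1 <- random_patches(img, size = 5, count = 4, seed = 99)
  p2 <- random_patches(img, size = 5, count = 4, seed = 99)
  expect_identical(lapply(p1, attr, "position"), lapply(p2, attr, "position"))
  expect_identical(p1[[2]]$pixels, p2[[2]]$pixels)
  for (p in p1) expect_equal(dim(p$pixels), c(3, 5, 5))
  # full-size patch is the image itself
  full <- random_patches(img, size = 20, count = 1, seed = 1)
  expect_identical(full[[1]]$pixels, img$pixels)
  expect_error(random_patches(img, size = 21, count = 1, seed = 1),
               "exceeds")
})

test_that("sliding-window tiling anchors the final row/column at the border", {
  img <- rand_image(1, 4, 4, seed = 8)
  expect_length(tile_patches(img, 2), 4)
  img5 <- rand_image(1, 5, 5, seed = 8)
  tiles <- tile_patches(img5, 2)
  expect_length(tiles, 9)
  offs <- t(vapply(tiles, attr, numeric(2), "position"))
  expect_setequal(unique(offs[, 1]), c(0, 2, 3))
  expect_setequal(unique(offs[, 2]), c(0, 2, 3))
  single <- tile_patches(img5, 5)
  expect_length(single, 1)
  expect_equal(unname(attr(single[[1]], "position")), c(0, 0))
})

test_that("stitching averages overlaps and errors on gaps", {
  # tile/stitch round trip, exact, over assorted sizes
  set.seed(9)
  for (case in 1:5) {
    h <- sample(3:17, 1)
    w <- sample(3:17, 1)
    s <- sample(2:min(h, w), 1)
    img <- rand_image(2, h, w, seed = case)
    back <- stitch_patches(tile_patches(img, s), h, w)
    expect_identical(back$pixels, img$pixels)
  }
  # overlap averaging: two patches valued 1 and 3 overlap in one column
  p1 <- multichannel_image(array(1, c(1, 2, 2)), "A")
  attr(p1, "position") <- c(0, 0)
  p2 <- multichannel_image(array(3, c(1, 2, 2)), "A")
  attr(p2, "position") <- c(0, 1)
  out <- stitch_patches(list(p1, p2), 2, 3)
  expect_equal(out$pixels[1, , 2], c(2, 2))
  expect_equal(out$pixels[1, , 1], c(1, 1))
  expect_equal(out$pixels[1, , 3], c(3, 3))
  # uncovered pixel is an error naming the gap
  expect_error(stitch_patches(list(p1), 2, 3), "uncovered")
})
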