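test_that("tiling covers the image with inward-shifted border patches", {
  img <- rgb_patch(array(runif(1000 * 1000 * 3) * 255, c(1000, 1000, 3)))
  tiles <- tile_patches(img, 384, 384)
  expect_length(tiles, 9L)
  origins <- t(vapply(tiles, function(p) p$origin, integer(2)))
  expect_setequal(origins[, 1], c(0L, 384L, 616L))
  expect_setequal(origins[, 2], c(0L, 384L, 616L))
  expect_true(all(vapply(tiles, function(p) all(dim(p$pixels)[1:2] == 384),
                         logical(1))))

  one <- tile_patches(rgb_patch(array(0, c(384, 384, 3))), 384, 100)
  expect_length(one, 1L)
  expect_identical(one[[1]]$origin, c(0L, 0L))

  expect_error(tile_patches(rgb_patch(array(0, c(200, 200, 3))), 384),
               class = "sunseg_size_error")
})

test_that("stitching averages overlaps and errors on gaps", {
  m <- matrix(runif(100), 10)
  expect_equal(stitch_patches(list(list(map = m, origin = c(0L, 0L))),
                              c(10L, 10L)), m)

  a <- matrix(0.2, 10, 6); b <- matrix(0.6, 10, 6)
  out <- stitch_patches(list(list(map = a, origin = c(0L, 0L)),
                             list(map = b, origin = c(0L, 4L))), c(10L, 10L))
  expect_equal(out[, 5:6], matrix(0.4, 10, 2))
  expect_equal(out[, 1:4], matrix(0.2, 10, 4))
  expect_equal(out[, 7:10], matrix(0.6, 10, 4))

  expect_error(stitch_patches(list(list(map = m, origin = c(5L, 0L))),
                              c(10L, 10L)), class = "sunseg_coverage_error")
  expect_error(stitch_patches(list(list(map = m, origin = c(0L, 0L))),
                              c(20L, 20L)), class = "sunseg_coverage_error")
})

test_that("tile then stitch reproduces the image exactly", {
  px <- array(runif(100 * 100 * 3), c(100, 100, 3))
  tiles <- tile_patches(rgb_patch(round(px * 255)), 40, 30)
  pieces <- lapply(tiles, function(p)
    list(map = p$pixels[, , 1], origin = p$origin))
  out <- stitch_patches(pieces, c(100L, 100L))
  expect_equal(out, round(px * 255)[, , 1])
})

test_that("pyramid has the four fixed levels with correct resampling", {
  pyr <- build_pyramid(rgb_patch(array(runif(384 * 384 * 3) * 255,
                                       c(384, 384, 3))))
  expect_equal(vapply(pyr, function(l) dim(l$pixels)[1], numeric(1)),
               c(480, 384, 288, 192))
  expect_equal(vapply(pyr, function(l) l$factor, numeric(1)),
               c(1.25, 1, 0.75, 0.5))

  const <- build_pyramid(rgb_patch(array(37, c(64, 64, 3))))
  for (l in const) expect_true(all(l$pixels == 37))

  x4 <- array(runif(64 * 64 * 4) * 255, c(64, 64, 4))
  x4[, , 4] <- (x4[, , 4] > 128) * 255
  pyr4 <- build_pyramid(x4)
  for (l in pyr4) expect_true(all(l$pixels[, , 4] %in% c(0, 255)))
})

test_that("image and mask files round-trip", {
  px <- round(array(runif(20 * 24 * 3) * 255, c(20, 24, 3)))
  f <- withr::local_tempfile(fileext = ".png")
  write_image(rgb_patch(px), f)
  expect_equal(read_image(f)$pixels, px)

  g <- withr::local_tempfile(fileext = ".png")
  gray <- matrix(runif(25), 5)
  png::writePNG(gray, g)
  rep3 <- read_image(g)
  expect_equal(rep3$pixels[, , 1], rep3$pixels[, , 2])
  expect_equal(rep3$pixels[, , 3], round(gray * 255))

  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(read_image(bad), class = "sunseg_format_error")
  expect_error(read_image("no/such/file.png"), class = "sunseg_format_error")

  mask <- matrix(runif(64) > 0.5, 8)
  mf <- withr::local_tempfile(fileext = ".png")
  write_mask(mask, mf)
  expect_identical(read_mask(mf), mask)

  lab <- matrix(sample.int(1000, 64), 8)
  lf <- withr::local_tempfile(fileext = ".tif")
  write_label_map(lab, lf)
  expect_identical(read_label_map(lf), lab)
})

test_that("RLE instance files preserve overlapping objects losslessly", {
  im <- instance_map(list(
    list(label_id = 2L, mask = rect_mask(16, 16, 2, 9, 2, 9)),
    list(label_id = 5L, mask = rect_mask(16, 16, 6, 13, 6, 13))))
  f <- withr::local_tempfile(fileext = ".csv")
  write_instances_rle(im, f)
  back <- read_instances_rle(f)
  expect_identical(back$shape, im$shape)
  expect_identical(lapply(back$objects, `[[`, "mask"),
                   lapply(im$objects, `[[`, "mask"))
  expect_identical(vapply(back$objects, `[[`, integer(1), "label_id"),
                   c(2L, 5L))
})

test_that("flattened rendering gives shared pixels to the lowest label", {
  im <- instance_map(list(
    list(label_id = 3L, mask = rect_mask(8, 8, 1, 5, 1, 5)),
    list(label_id = 7L, mask = rect_mask(8, 8, 4, 8, 4, 8))))
  flat <- flatten_instances(im)
  expect_equal(flat[4, 4], 3L)
  expect_equal(flat[5, 5], 3L)  # shared pixel -> lowest id
  expect_equal(flat[6, 6], 7L)
  expect_equal(flat[1, 8], 0L)
})
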