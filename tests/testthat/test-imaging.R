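test_that("discriminant index matches direct arithmetic at anchor pixels", {
  expect_identical(discriminant_index(100, 100), 128)
  expect_identical(discriminant_index(0, 255), 256)
  expect_identical(discriminant_index(255, 0), 0)
  expect_equal(discriminant_index(50, 100), 128 + 128 * 50 / 150)
  expect_identical(discriminant_index(61, 67), 134)  # exact boundary pixel
  expect_identical(discriminant_index(0, 0), 128)    # black is neutral
})

test_that("discriminant index rejects out-of-range channels", {
  expect_error(discriminant_index(-1, 10), "0, 255")
  expect_error(discriminant_index(10, 256), "0, 255")
  expect_error(discriminant_index(NA_real_, 10), "NA")
})

test_that("index is antisymmetric about 128 and monotone in green", {
  set.seed(42)
  r <- sample(0:255, 400, replace = TRUE)
  g <- sample(0:255, 400, replace = TRUE)
  keep <- r + g > 0
  expect_equal(discriminant_index(r[keep], g[keep]) +
                 discriminant_index(g[keep], r[keep]),
               rep(256, sum(keep)), tolerance = 1e-9)
  # fixed r, increasing g: index never decreases
  for (rr in c(0L, 17L, 128L, 255L)) {
    idx <- discriminant_index(rep(rr, 256), 0:255)
    expect_true(all(diff(idx) >= 0))
  }
  # gray pixels are neutral and non-vegetation at the working threshold
  grays <- discriminant_index(0:255, 0:255)
  expect_true(all(grays == 128))
})

test_that("segmentation is inclusive at the threshold and ignores blue", {
  expect_false(any(segment_canopy(uniform_image(c(120, 120, 120)))))
  strip <- pixel_strip(list(c(0, 255, 0),    # index 256
                            c(61, 67, 200),  # exactly 134 -> vegetation
                            c(62, 67, 0),    # ~132.96 -> background
                            c(0, 0, 255)))   # pure blue: neutral 128
  expect_identical(as.vector(segment_canopy(strip)), c(TRUE, TRUE, FALSE, FALSE))
  # blue channel must not influence the decision
  strip_b <- pixel_strip(list(c(0, 255, 255), c(61, 67, 0),
                              c(62, 67, 255), c(0, 0, 0)))
  expect_identical(as.vector(segment_canopy(strip_b)),
                   as.vector(segment_canopy(strip)))
})

test_that("once vegetation, increasing green never declassifies a pixel", {
  for (rr in c(10L, 61L, 140L)) {
    cls <- as.vector(segment_canopy(pixel_strip(
      lapply(0:255, function(gg) c(rr, gg, 0)))))
    expect_true(all(diff(cls) >= 0))  # FALSE..FALSE TRUE..TRUE pattern
  }
})

test_that("cover ratio is the exact vegetation pixel share", {
  m <- matrix(TRUE, 10, 10)
  expect_equal(cover_ratio(m)$cover_percent, 100)
  m[] <- FALSE
  expect_equal(cover_ratio(m)$cover_percent, 0)
  m[1:25] <- TRUE
  cv <- cover_ratio(m)
  expect_equal(cv$cover_percent, 25)
  expect_equal(cv$vegetation_pixels, 25L)
  expect_equal(cv$total_pixels, 100L)
  # exactness for arbitrary counts
  set.seed(7)
  for (k in sample(0:400, 10)) {
    mm <- matrix(FALSE, 20, 20)
    if (k > 0) mm[sample(400, k)] <- TRUE
    expect_identical(cover_ratio(mm)$cover_percent, 100 * k / 400)
  }
  expect_error(cover_ratio(matrix(logical(0), 0, 0)), "at least one pixel")
})

test_that("PNG images round-trip losslessly through load_image", {
  arr <- array(as.integer(c(10, 200, 61, 0,   # R
                            20, 100, 67, 0,   # G
                            30, 50, 255, 0)), dim = c(2, 2, 3))
  img <- rgb_image(arr)
  path <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, path)
  reloaded <- load_image(path)
  expect_identical(unclass(reloaded), unclass(img))
})

test_that("grayscale PNG is promoted to equal R=G=B and alpha is dropped", {
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(120 / 255, 3, 4), target = path)
  img <- load_image(path)
  expect_true(all(img == 120L))
  expect_identical(dim(img), c(3L, 4L, 3L))
  # RGBA: alpha plane must be discarded, colour planes kept
  rgba <- array(c(rep(c(0.2, 0.6, 0.1), each = 6), rep(0.5, 6)),
                dim = c(2, 3, 4))
  png::writePNG(rgba, target = path)
  img2 <- load_image(path)
  expect_identical(dim(img2), c(2L, 3L, 3L))
  expect_identical(unique(as.vector(img2[, , 1])), as.integer(round(0.2 * 255)))
})

test_that("corrupt or unsupported files signal errors", {
  path <- withr::local_tempfile(fileext = ".png")
  writeLines("not an image", path)
  expect_error(load_image(path), "unsupported image format")
  # truncated PNG: valid magic, unreadable body
  good <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), target = good)
  bytes <- readBin(good, "raw", n = file.size(good))
  writeBin(bytes[1:20], path)
  expect_error(load_image(path), "cannot decode PNG")
  expect_error(load_image(file.path(tempdir(), "nope-does-not-exist.png")),
               "not found")
})

test_that("mask PNG export renders vegetation white on black", {
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(mask, path)
  out <- png::readPNG(path)
  expect_identical(out == 1, mask)
})

test_that("rgb_image validates its invariants", {
  expect_error(rgb_image(array(0L, c(2, 2, 2))), "height x width x 3")
  expect_error(rgb_image(array(-1L, c(2, 2, 3))), "0, 255")
  expect_error(rgb_image(array(300L, c(2, 2, 3))), "0, 255")
  expect_error(rgb_image(array(0.5, c(2, 2, 3))), "whole numbers")
})
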