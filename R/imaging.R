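#' Red-green discriminant index of a pixel
#'
#' Computes the per-pixel greenness score
#' \deqn{I = 128 + 128\,(G - R)/(G + R)}
#' used to separate rice leaf and stem pixels from soil, water and straw.
#' The index is centred at 128 for achromatic pixels (R = G), rises to 256
#' for pure green and falls to 0 for pure red. The blue channel plays no
#' part in the classification. Pixels with \eqn{I \ge 134} are treated as
#' vegetation by [segment_canopy()].
#'
#' @param r,g Red and green channel intensities, integers (or integer-valued
#'   doubles) in \[0, 255\]. Vectors are recycled to a common length.
#' @return Numeric vector of index values in \[0, 256\], unrounded. Pixels
#'   with `r + g == 0` (pure black or pure blue) return the neutral value
#'   128, so they are never classified as vegetation at the default
#'   threshold.
#' @examples
#' discriminant_index(100, 100)  # 128, achromatic
#' discriminant_index(0, 255)    # 256, pure green
#' discriminant_index(61, 67)    # exactly 134, the classification boundary
#' @export
discriminant_index <- function(r, g) {
  if (!is.numeric(r) || !is.numeric(g)) {
    stop("channel intensities must be numeric", call. = FALSE)
  }
  if (anyNA(r) || anyNA(g)) stop("channel intensities contain NA", call. = FALSE)
  if (any(r < 0 | r > 255) || any(g < 0 | g > 255)) {
    stop("channel intensities must lie in [0, 255]", call. = FALSE)
  }
  s <- r + g
  idx <- rep(128, length.out = max(length(r), length(g)))
  ok <- s > 0
  idx[ok] <- 128 + 128 * (g - r)[ok] / s[ok]
  idx
}

#' Construct an RGB image object
#'
#' Light container for an 8-bit three-channel raster: an integer array of
#' shape height x width x 3 with values in \[0, 255\], row-major in the
#' usual R raster sense (first index = image row from the top).
#'
#' @param pixels Numeric array `c(height, width, 3)` with integer values in
#'   \[0, 255\], channels ordered R, G, B.
#' @return An object of class `rgb_image`: the validated array with
#'   attributes `width` and `height`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("pixels must be a height x width x 3 array", call. = FALSE)
  }
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L) stop("image must have at least one pixel", call. = FALSE)
  if (anyNA(pixels)) stop("pixel values contain NA", call. = FALSE)
  if (any(pixels < 0 | pixels > 255)) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  if (any(pixels != round(pixels))) {
    stop("pixel values must be whole numbers (8-bit intensities)", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(pixels,
            class = "rgb_image",
            width = d[2], height = d[1])
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d px>\n", attr(x, "width"), attr(x, "height")))
  invisible(x)
}

#' Load a canopy image from PNG or JPEG
#'
#' Decodes an 8-bit RGB raster. An alpha channel, if present, is dropped;
#' grayscale images are promoted to R = G = B. Format is detected from the
#' file's magic bytes, not its extension.
#'
#' Note that JPEG is lossy and decoders differ in IDCT rounding, so cover
#' values computed from JPEG input may differ at the margin between
#' platforms; PNG round-trips are bit-exact.
#'
#' @param path Path to a PNG or JPEG file.
#' @return An [rgb_image()] object.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("path must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 3L)
  raster <- if (length(magic) >= 3L && identical(magic[1:3], as.raw(c(0x89, 0x50, 0x4e)))) {
    tryCatch(png::readPNG(path), error = function(e)
      stop("cannot decode PNG file '", path, "': ", conditionMessage(e), call. = FALSE))
  } else if (length(magic) >= 2L && identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
    tryCatch(jpeg::readJPEG(path), error = function(e)
      stop("cannot decode JPEG file '", path, "': ", conditionMessage(e), call. = FALSE))
  } else {
    stop("unsupported image format (expected PNG or JPEG): ", path, call. = FALSE)
  }
  # readPNG/readJPEG return doubles in [0,1]; 16-bit PNGs yield values that
  # are not multiples of 1/255, which we reject rather than silently requantize
  if (length(dim(raster)) == 2L) {
    raster <- array(rep(raster, 3L), dim = c(dim(raster), 3L))
  }
  nch <- dim(raster)[3]
  if (nch == 2L) raster <- array(rep(raster[, , 1L], 3L), dim = c(dim(raster)[1:2], 3L))
  if (dim(raster)[3] >= 4L) raster <- raster[, , 1:3, drop = FALSE]
  vals <- raster * 255
  if (max(abs(vals - round(vals))) > 1e-6) {
    stop("unsupported bit depth (expected 8-bit channels): ", path, call. = FALSE)
  }
  rgb_image(round(vals))
}

#' Segment vegetation pixels by the red-green discriminant index
#'
#' Classifies each pixel of a canopy image as rice leaf/stem (vegetation)
#' or background by thresholding the [discriminant_index()]. The comparison
#' is inclusive: a pixel whose index equals the threshold counts as
#' vegetation. The default threshold of 134 is the operational value for
#' rice canopies photographed from above; the blue channel is ignored.
#'
#' @param image An [rgb_image()] object.
#' @param threshold Classification threshold on the index, in \[0, 256\].
#'   Default 134.
#' @return A `binary_mask`: logical matrix (height x width), `TRUE` where
#'   vegetation.
#' @examples
#' px <- array(c(61, 67, 200), dim = c(1, 1, 3))
#' segment_canopy(rgb_image(px))  # TRUE: index is exactly 134
#' @export
segment_canopy <- function(image, threshold = 134) {
  if (!inherits(image, "rgb_image")) {
    stop("image must be an rgb_image object", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0 || threshold > 256) {
    stop("threshold must be a single number in [0, 256]", call. = FALSE)
  }
  idx <- discriminant_index(as.numeric(image[, , 1L]), as.numeric(image[, , 2L]))
  mask <- matrix(idx >= threshold, nrow = dim(image)[1], ncol = dim(image)[2])
  structure(mask, class = c("binary_mask", class(mask)))
}

#' Canopy cover from a segmentation mask
#'
#' @param mask Logical matrix as returned by [segment_canopy()];
#'   `TRUE` = vegetation.
#' @return A list of class `cover_result` with `vegetation_pixels`,
#'   `total_pixels` and `cover_percent` (= 100 * vegetation / total).
#' @export
cover_ratio <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  n <- length(mask)
  if (n < 1L) stop("mask must contain at least one pixel", call. = FALSE)
  if (anyNA(mask)) stop("mask contains NA flags", call. = FALSE)
  k <- sum(mask)
  structure(
    list(vegetation_pixels = k, total_pixels = n,
         cover_percent = 100 * k / n),
    class = "cover_result"
  )
}

#' @export
print.cover_result <- function(x, ...) {
  cat(sprintf("Canopy cover: %.1f%% (%d / %d px vegetation)\n",
              x$cover_percent, x$vegetation_pixels, x$total_pixels))
  invisible(x)
}

#' Write a segmentation mask as an 8-bit PNG
#'
#' Vegetation pixels are rendered white (255) on a black background, the
#' conventional display of the binarized canopy.
#'
#' @param mask Logical matrix from [segment_canopy()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  png::writePNG(matrix(as.numeric(mask), nrow = nrow(mask)), target = path)
  invisible(path)
}

#' Write an RGB image object as PNG
#'
#' @param image An [rgb_image()] object.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  if (!inherits(image, "rgb_image")) {
    stop("image must be an rgb_image object", call. = FALSE)
  }
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}
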