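#' Grayscale image with physical pixel size
#'
#' Thin container used throughout the pipeline: a numeric matrix (rows = y,
#' row 1 at the top, columns = x), a declared bit depth and the physical pixel
#' size in micrometers. 8-bit images hold integers 0..255, 16-bit images
#' 0..65535, `"float"` images any non-negative values.
#'
#' @param grid numeric matrix.
#' @param bit_depth one of `"8"`, `"16"`, `"float"`.
#' @param pixel_size pixel edge length in micrometers (> 0).
#' @return object of class `GrayImage`.
#' @export
gray_image <- function(grid, bit_depth = c("float", "8", "16"),
                       pixel_size = 1) {
  bit_depth <- match.arg(as.character(bit_depth), c("float", "8", "16"))
  stopifnot(is.matrix(grid), is.numeric(grid))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (micrometers)")
  rng <- range(grid, finite = TRUE)
  lim <- switch(bit_depth, "8" = 255, "16" = 65535, "float" = Inf)
  if (length(grid) && (rng[1] < 0 || rng[2] > lim))
    stop(sprintf("values outside the declared %s-bit range", bit_depth))
  structure(list(grid = grid, bit_depth = bit_depth, pixel_size = pixel_size),
            class = "GrayImage")
}

#' @export
print.GrayImage <- function(x, ...) {
  cat(sprintf("GrayImage %d x %d px, %s-bit, %.3g um/px, range [%.3g, %.3g]\n",
              nrow(x$grid), ncol(x$grid), x$bit_depth, x$pixel_size,
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.GrayImage <- function(x) dim(x$grid)

#' Read a grayscale image from PNG or TIFF
#'
#' PNG/TIFF samples in [0, 1] are rescaled to the requested bit depth.
#' Multi-channel images are averaged to one channel.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param bit_depth declared bit depth of the result.
#' @param pixel_size physical pixel size in micrometers.
#' @return `GrayImage`.
#' @export
read_gray_image <- function(path, bit_depth = "8", pixel_size = 1) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  scale <- switch(as.character(bit_depth), "8" = 255, "16" = 65535, 1)
  grid <- if (bit_depth == "float") arr else round(arr * scale)
  gray_image(grid, bit_depth, pixel_size)
}

#' Write a grayscale image to PNG or TIFF
#'
#' 8/16-bit images are scaled into [0, 1] by their nominal range; float
#' images by their maximum (TIFF float storage is only defined on [0, 1], so
#' `normalize = FALSE` clamps instead of rescaling).
#'
#' @param image `GrayImage` or numeric matrix.
#' @param path output file (.png, .tif or .tiff).
#' @param normalize for float input, divide by the image maximum first.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, normalize = TRUE) {
  if (inherits(image, "GrayImage")) {
    g <- image$grid
    scale <- switch(image$bit_depth, "8" = 255, "16" = 65535, "float" = NA)
  } else {
    g <- image; scale <- NA
  }
  ext <- tolower(tools::file_ext(path))
  if (is.na(scale)) {
    if (normalize) g <- g / max(g, 1e-12)
  } else {
    g <- g / scale
  }
  g <- pmin(pmax(g, 0), 1)
  switch(ext,
    png = png::writePNG(g, path),
    tif = ,
    tiff = tiff::writeTIFF(g, path,
                           bits.per.sample = if (identical(scale, 65535)) 16L else 8L),
    stop("unsupported image format: ", ext))
  invisible(path)
}
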