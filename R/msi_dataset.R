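#' Gridded MSI dataset (pixel spectra on a regular raster)
#'
#' The in-memory representation of an imzML dataset: integer pixel
#' coordinates on a rectangular grid (0-based, x rightwards, y downwards,
#' origin top-left), one centroided spectrum per pixel (strictly increasing
#' m/z, non-negative intensities), the physical pixel pitch and the acquired
#' mass range.
#'
#' @param coords data.frame with integer columns `x`, `y` (0-based indices),
#'   one row per acquired pixel; duplicates are rejected.
#' @param mz list of numeric vectors, one per pixel, strictly increasing.
#' @param intensity list of numeric vectors parallel to `mz`, all >= 0.
#' @param pixel_size lateral resolution in micrometers (default 20).
#' @param mz_range acquired mass range in Da (default `c(500, 4500)`); every
#'   m/z must fall inside it.
#' @param normalization `"raw"` or `"TIC"`.
#' @return object of class `MSIDataset`.
#' @export
msi_dataset <- function(coords, mz, intensity, pixel_size = 20,
                        mz_range = c(500, 4500),
                        normalization = c("raw", "TIC")) {
  normalization <- match.arg(normalization)
  coords <- as.data.frame(coords)
  stopifnot(all(c("x", "y") %in% names(coords)))
  coords$x <- as.integer(coords$x); coords$y <- as.integer(coords$y)
  n <- nrow(coords)
  if (length(mz) != n || length(intensity) != n)
    stop("coords, mz and intensity must describe the same number of pixels")
  if (any(coords$x < 0L) || any(coords$y < 0L))
    stop("pixel indices must be >= 0 (internal 0-based convention)")
  if (anyDuplicated(coords[, c("x", "y")]))
    stop("duplicate pixel coordinates")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (length(mz_range) != 2L || mz_range[1] >= mz_range[2])
    stop("mz_range must be (low, high) with low < high")
  for (i in seq_len(n)) {
    mi <- mz[[i]]; ii <- intensity[[i]]
    if (length(mi) != length(ii))
      stop(sprintf("pixel %d: m/z and intensity lengths differ", i))
    if (length(mi)) {
      if (any(diff(mi) <= 0))
        stop(sprintf("pixel %d: m/z values must be strictly increasing", i))
      if (any(ii < 0)) stop(sprintf("pixel %d: negative intensity", i))
      if (mi[1] < mz_range[1] || mi[length(mi)] > mz_range[2])
        stop(sprintf("pixel %d: m/z outside the acquired range", i))
    }
  }
  structure(list(coords = coords, mz = mz, intensity = intensity,
                 pixel_size = pixel_size, mz_range = mz_range,
                 normalization = normalization),
            class = "MSIDataset")
}

#' @export
print.MSIDataset <- function(x, ...) {
  cat(sprintf("MSIDataset: %d pixels, %.0f um pitch, m/z %.0f-%.0f, %s\n",
              nrow(x$coords), x$pixel_size, x$mz_range[1], x$mz_range[2],
              x$normalization))
  invisible(x)
}

n_pixels <- function(dataset) nrow(dataset$coords)

#' Total-ion-count normalize an MSI dataset
#'
#' Divides every spectrum by its intensity sum so that pixels become
#' comparable. Spectra whose total ion count is zero are left as zeros and
#' reported in the `"zero_tic_pixels"` attribute of the result. A dataset
#' already flagged as TIC-normalized is rejected.
#'
#' @param dataset `MSIDataset` with `normalization == "raw"`.
#' @return TIC-normalized `MSIDataset` (every non-empty spectrum sums to 1).
#' @export
tic_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "MSIDataset"))
  if (dataset$normalization != "raw")
    stop("dataset is already TIC-normalized")
  tic <- vapply(dataset$intensity, sum, 0)
  zero <- which(tic == 0)
  dataset$intensity <- lapply(seq_along(dataset$intensity), function(i) {
    if (tic[i] > 0) dataset$intensity[[i]] / tic[i] else dataset$intensity[[i]]
  })
  dataset$normalization <- "TIC"
  attr(dataset, "zero_tic_pixels") <- dataset$coords[zero, , drop = FALSE]
  dataset
}

#' Extract an ion image for one target m/z window
#'
#' Pixel value = sum (or max) of spectral intensities with
#' |m/z - target| <= tolerance, window ends inclusive. Grid cells that were
#' never acquired (off-tissue) are 0 and marked in the acquisition mask.
#'
#' @param dataset `MSIDataset`.
#' @param target_mz window center in Da; must lie inside `mz_range`.
#' @param tolerance half-width, > 0.
#' @param unit `"Da"` or `"ppm"` (ppm converts to Da at the target).
#' @param aggregate `"sum"` (area-like, default) or `"max"`.
#' @return object of class `IonImage`: list with `grid` (rows = y), `mask`
#'   (acquired pixels), `target_mz`, `tolerance` (Da), `max_intensity`,
#'   `normalization`, `pixel_size`.
#' @export
extract_ion_image <- function(dataset, target_mz, tolerance = 0.25,
                              unit = c("Da", "ppm"),
                              aggregate = c("sum", "max")) {
  stopifnot(inherits(dataset, "MSIDataset"))
  unit <- match.arg(unit); aggregate <- match.arg(aggregate)
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (target_mz < dataset$mz_range[1] || target_mz > dataset$mz_range[2])
    stop("target_mz outside the acquired mass range")
  tol_da <- if (unit == "ppm") target_mz * tolerance * 1e-6 else tolerance
  nx <- max(dataset$coords$x) + 1L
  ny <- max(dataset$coords$y) + 1L
  grid <- matrix(0, ny, nx)
  mask <- matrix(FALSE, ny, nx)
  agg <- if (aggregate == "sum") sum else max
  for (i in seq_len(n_pixels(dataset))) {
    m <- dataset$mz[[i]]
    sel <- m >= target_mz - tol_da & m <= target_mz + tol_da
    v <- if (any(sel)) agg(dataset$intensity[[i]][sel]) else 0
    r <- dataset$coords$y[i] + 1L; c <- dataset$coords$x[i] + 1L
    grid[r, c] <- v
    mask[r, c] <- TRUE
  }
  structure(list(grid = grid, mask = mask, target_mz = target_mz,
                 tolerance = tol_da, max_intensity = max(grid),
                 normalization = dataset$normalization,
                 pixel_size = dataset$pixel_size),
            class = "IonImage")
}

#' @export
print.IonImage <- function(x, ...) {
  cat(sprintf("IonImage m/z %.4f +/- %.3f Da, %d x %d px, max %.4g (%s)\n",
              x$target_mz, x$tolerance, nrow(x$grid), ncol(x$grid),
              x$max_intensity, x$normalization))
  invisible(x)
}

#' Average spectrum over all pixels on a common m/z binning
#'
#' Intensities are accumulated into fixed-width bins spanning the acquired
#' mass range and divided by the number of pixels (pixels without signal in a
#' bin contribute zero).
#'
#' @param dataset `MSIDataset` with at least one pixel.
#' @param bin_width bin width in Da (default 0.1).
#' @return data.frame with `mz` (bin centers) and `intensity` (mean per
#'   pixel), restricted to non-empty bins.
#' @export
average_spectrum <- function(dataset, bin_width = 0.1) {
  stopifnot(inherits(dataset, "MSIDataset"))
  if (n_pixels(dataset) == 0L) stop("dataset has no pixels")
  if (bin_width <= 0) stop("bin_width must be > 0")
  lo <- dataset$mz_range[1]
  nbin <- ceiling((dataset$mz_range[2] - lo) / bin_width) + 1L
  acc <- numeric(nbin)
  for (i in seq_len(n_pixels(dataset))) {
    m <- dataset$mz[[i]]
    if (!length(m)) next
    b <- pmin(floor((m - lo) / bin_width) + 1L, nbin)
    s <- tapply(dataset$intensity[[i]], b, sum)
    idx <- as.integer(names(s))
    acc[idx] <- acc[idx] + as.numeric(s)
  }
  keep <- which(acc > 0)
  data.frame(mz = lo + (keep - 0.5) * bin_width,
             intensity = acc[keep] / n_pixels(dataset))
}

#' Export an ion image as float TIFF + PNG preview + JSON sidecar
#'
#' Writes `<prefix>.tif` (32-bit float, intensities divided by the image
#' maximum because TIFF float storage is defined on [0, 1]), `<prefix>.png`
#' (8-bit preview on the same scale) and `<prefix>.json` recording target
#' m/z, tolerance, the max intensity needed to undo the scaling, and the
#' normalization state.
#'
#' @param image `IonImage`.
#' @param prefix output path prefix (no extension).
#' @return named character vector of the files written, invisibly.
#' @export
write_ion_image <- function(image, prefix) {
  stopifnot(inherits(image, "IonImage"))
  tif <- paste0(prefix, ".tif"); pngf <- paste0(prefix, ".png")
  jsonf <- paste0(prefix, ".json")
  scale <- max(image$max_intensity, 1e-12)
  tiff::writeTIFF(image$grid / scale, tif, bits.per.sample = 32L,
                  reduce = FALSE)
  png::writePNG(image$grid / scale, pngf)
  jsonlite::write_json(list(target_mz = image$target_mz,
                            tolerance = image$tolerance,
                            max_intensity = image$max_intensity,
                            normalization = image$normalization,
                            pixel_size = image$pixel_size),
                       jsonf, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = tif, png = pngf, json = jsonf))
}
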