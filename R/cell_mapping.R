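#' Segment fluorescent peptidergic cells
#'
#' Thresholds a background-subtracted fluorescence image (Otsu by default),
#' labels 8-connected components and keeps those whose equivalent diameter
#' (diameter of the circle with the same area) lies within the physical size
#' range of the neurons, 5-14 micrometers by default.
#'
#' @param fluor 8-bit `GrayImage` with a physical `pixel_size` (required for
#'   the diameter filter).
#' @param d_min,d_max equivalent-diameter bounds in micrometers.
#' @param threshold `"otsu"` or a numeric cutoff on the 0..255 scale.
#' @return object of class `CellLabelMap`: list with `grid` (integer labels,
#'   0 = background, labels contiguous 1..n_cells), `n_cells`, `cells`
#'   (data.frame: `label`, `area_px`, `cx_um`, `cy_um`, `diameter_um`) and
#'   `pixel_size`.
#' @export
segment_fluorescent_cells <- function(fluor, d_min = 5, d_max = 14,
                                      threshold = "otsu") {
  stopifnot(inherits(fluor, "GrayImage"))
  if (is.null(fluor$pixel_size) || !is.finite(fluor$pixel_size))
    stop("pixel_size missing: diameters need physical units")
  if (fluor$bit_depth != "8")
    stop("segmentation expects a background-subtracted 8-bit image")
  g <- fluor$grid
  th <- if (identical(threshold, "otsu")) {
    255 * EBImage::otsu(EBImage::Image(g / 255), range = c(0, 1))
  } else as.numeric(threshold)
  mask <- g > th
  lab <- label_connected(mask, connectivity = 8)
  ps <- fluor$pixel_size
  n0 <- max(lab)
  cells <- data.frame(label = integer(), area_px = integer(),
                      cx_um = numeric(), cy_um = numeric(),
                      diameter_um = numeric())
  if (n0 > 0) {
    idx <- which(lab > 0)
    l <- lab[idx]
    r <- (idx - 1L) %% nrow(g) + 1L
    c <- (idx - 1L) %/% nrow(g) + 1L
    area <- tabulate(l, n0)
    diam <- 2 * sqrt(area / pi) * ps
    keep <- which(diam >= d_min & diam <= d_max)
    relabel <- integer(n0)
    relabel[keep] <- seq_along(keep)
    new_lab <- matrix(0L, nrow(g), ncol(g))
    sel <- relabel[l] > 0L
    new_lab[idx[sel]] <- relabel[l[sel]]
    lab <- new_lab
    if (length(keep)) {
      cells <- data.frame(
        label = seq_along(keep),
        area_px = area[keep],
        cx_um = as.numeric(tapply((c - 0.5) * ps, l, mean)[as.character(keep)]),
        cy_um = as.numeric(tapply((r - 0.5) * ps, l, mean)[as.character(keep)]),
        diameter_um = diam[keep])
    }
  }
  structure(list(grid = lab, n_cells = nrow(cells), cells = cells,
                 pixel_size = ps, threshold = th),
            class = "CellLabelMap")
}

#' @export
print.CellLabelMap <- function(x, ...) {
  cat(sprintf("CellLabelMap: %d cells on %d x %d px (%.3g um/px)\n",
              x$n_cells, nrow(x$grid), ncol(x$grid), x$pixel_size))
  invisible(x)
}

#' Integrate an ion image with the cell reference layer
#'
#' Resamples the MSI-grid ion image onto the microscopy grid through the
#' rigid transform with bilinear (linear) interpolation, masks it to the
#' segmented cell pixels and quantizes to 8 bit using the section-wise
#' maximum (or a supplied global maximum for cross-section comparability).
#'
#' @param ion_image `IonImage` on the MSI grid.
#' @param transform `TransformSpec` mapping the MSI frame onto the microscopy
#'   frame.
#' @param cells `CellLabelMap` on the microscopy grid.
#' @param peptide,section_id labels carried on the result.
#' @param scale_max intensity mapped to 255; defaults to the maximum of the
#'   masked resampled image (the section-wise max).
#' @return object of class `MappingImage`: 8-bit cell-masked peptide map with
#'   fields `grid`, `peptide`, `section_id`, `scale_max`, `pixel_size`;
#'   attribute `"empty"` is TRUE when no cell carries signal.
#' @export
integrate_mapping <- function(ion_image, transform, cells,
                              peptide = NA_character_,
                              section_id = NA_character_,
                              scale_max = NULL) {
  stopifnot(inherits(ion_image, "IonImage"),
            inherits(transform, "TransformSpec"),
            inherits(cells, "CellLabelMap"))
  src <- gray_image(ion_image$grid, "float", ion_image$pixel_size)
  res <- apply_rigid_transform(src, transform, dim(cells$grid),
                               cells$pixel_size)
  masked <- res$grid * (cells$grid > 0)
  m <- scale_max %||% max(masked)
  empty <- !is.finite(m) || m <= 0
  grid8 <- if (empty) matrix(0L, nrow(masked), ncol(masked))
           else matrix(as.integer(round(255 * pmin(masked / m, 1))),
                       nrow(masked), ncol(masked))
  out <- structure(list(grid = grid8, peptide = peptide,
                        section_id = section_id,
                        scale_max = if (empty) 0 else m,
                        pixel_size = cells$pixel_size,
                        continuous = masked),
                   class = "MappingImage")
  attr(out, "empty") <- empty || cells$n_cells == 0L
  out
}

#' @export
print.MappingImage <- function(x, ...) {
  cat(sprintf("MappingImage '%s' section '%s': %d x %d px, scale max %.4g\n",
              x$peptide, x$section_id, nrow(x$grid), ncol(x$grid),
              x$scale_max))
  invisible(x)
}

#' Additively blend pseudocolored mapping images
#'
#' Each mapping layer is tinted with its peptide color and the layers are
#' summed channel-wise with clipping at 255.
#'
#' @param mappings list of `MappingImage` of identical shape.
#' @param colors per-layer colors (any form `grDevices::col2rgb` accepts),
#'   recycled against the layers by name when named.
#' @return integer array (rows, cols, 3) in 0..255 with attribute
#'   `"legend"` (data.frame peptide/color).
#' @export
render_composite <- function(mappings, colors) {
  if (!length(mappings)) stop("no mapping images")
  shapes <- vapply(mappings, function(m) paste(dim(m$grid), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) stop("mapping shapes differ")
  peps <- vapply(mappings, function(m) m$peptide, "")
  if (!is.null(names(colors)) && all(peps %in% names(colors)))
    colors <- colors[peps]
  if (length(colors) != length(mappings))
    stop("need one color per mapping")
  d <- dim(mappings[[1]]$grid)
  out <- array(0, c(d, 3L))
  for (i in seq_along(mappings)) {
    rgb <- grDevices::col2rgb(colors[i])[, 1] / 255
    for (ch in 1:3)
      out[, , ch] <- out[, , ch] + mappings[[i]]$grid * rgb[ch]
  }
  out <- array(as.integer(pmin(round(out), 255)), dim(out))
  attr(out, "legend") <- data.frame(peptide = peps,
                                    color = as.character(colors))
  out
}

#' Export mapping images as a multi-page TIFF layer stack
#'
#' One 8-bit grayscale page per peptide, in peptide-table order, plus a JSON
#' sidecar (`<path>.json`) holding the page names, since baseline TIFF page
#' description tags are not preserved by the TIFF writer.
#'
#' @param mappings list of `MappingImage` of identical shape with unique
#'   peptide names.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
export_layer_stack <- function(mappings, path) {
  if (!length(mappings)) stop("no mapping images to export")
  shapes <- vapply(mappings, function(m) paste(dim(m$grid), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) stop("mapping shapes differ")
  peps <- vapply(mappings, function(m) m$peptide, "")
  if (anyDuplicated(peps)) stop("duplicate peptide names in layer stack")
  pages <- lapply(mappings, function(m) m$grid / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(pages = peps),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' Read back a layer stack written by [export_layer_stack()]
#'
#' @param path multi-page TIFF path (sidecar `<path>.json` supplies names).
#' @return named list of 8-bit integer matrices.
#' @export
read_layer_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  names_file <- paste0(path, ".json")
  nm <- if (file.exists(names_file))
    unlist(jsonlite::read_json(names_file)$pages)
  else paste0("page", seq_along(pages))
  out <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    matrix(as.integer(round(p * 255)), nrow(p), ncol(p))
  })
  names(out) <- nm
  out
}
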