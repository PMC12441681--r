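#' Convert an 8-bit mapping image to 16 bit
#'
#' Multiplies by 257 so that 0 maps to 0 and 255 to 65535, matching the
#' standard 8-to-16-bit promotion used before intermodes/fixed-range
#' binarization.
#'
#' @param mapping `MappingImage` or 8-bit `GrayImage`.
#' @return 16-bit `GrayImage`.
#' @export
to_16bit <- function(mapping) {
  if (inherits(mapping, "MappingImage")) {
    g <- mapping$grid; ps <- mapping$pixel_size
  } else if (inherits(mapping, "GrayImage")) {
    if (mapping$bit_depth != "8") stop("to_16bit expects an 8-bit image")
    g <- mapping$grid; ps <- mapping$pixel_size
  } else stop("to_16bit expects a MappingImage or 8-bit GrayImage")
  if (any(g < 0 | g > 255)) stop("to_16bit expects 8-bit values (0..255)")
  gray_image(g * 257, "16", ps)
}

#' Intermodes automatic threshold of a 16-bit image
#'
#' The 16-bit values are binned down to 256 histogram levels; the histogram is
#' repeatedly smoothed with a 3-bin running mean until exactly two local
#' maxima remain, and the threshold is the midpoint of the two modes, rescaled
#' back to the 16-bit range (x 257). Histograms that never become bimodal
#' (e.g. a constant image) raise an error so the caller can fall back to the
#' fixed range.
#'
#' @param image16 16-bit `GrayImage` or numeric matrix of 0..65535 values.
#' @param max_iter smoothing iteration cap (default 10000).
#' @return threshold on the 16-bit scale.
#' @export
threshold_intermodes <- function(image16, max_iter = 10000) {
  g <- if (inherits(image16, "GrayImage")) image16$grid else image16
  lev <- pmin(pmax(floor(g / 257), 0), 255)
  h <- tabulate(as.vector(lev) + 1L, 256)
  h <- as.numeric(h)
  modes <- function(x) which(diff(sign(diff(c(-Inf, x, -Inf)))) == -2)
  it <- 0
  while (length(modes(h)) > 2) {
    h <- (c(0, h[-256]) + h + c(h[-1], 0)) / 3
    it <- it + 1
    if (it > max_iter)
      stop("histogram did not become bimodal within ", max_iter, " iterations")
  }
  m <- modes(h)
  if (length(m) != 2)
    stop("histogram is unimodal; intermodes threshold undefined")
  # modes are 1-based bin indices of levels 0..255
  floor(((m[1] - 1) + (m[2] - 1)) / 2) * 257
}

#' Binarize a 16-bit image with an inclusive intensity range
#'
#' Foreground are pixels with `lo <= value <= hi`, both ends inclusive; the
#' default range 8400-65535 reproduces the fixed operating range used for
#' peptide mapping stacks.
#'
#' @param image16 16-bit `GrayImage` or numeric matrix.
#' @param lo,hi inclusive bounds, `0 <= lo <= hi <= 65535`.
#' @param peptide,section_id labels carried on the mask.
#' @return object of class `BinaryMask`: list with logical `grid`, `area`
#'   (foreground pixel count), `peptide`, `section_id`.
#' @export
binarize <- function(image16, lo = 8400, hi = 65535,
                     peptide = NA_character_, section_id = NA_character_) {
  g <- if (inherits(image16, "GrayImage")) image16$grid else image16
  if (!(lo <= hi)) stop("lo must be <= hi")
  if (lo < 0 || hi > 65535) stop("bounds must lie in 0..65535")
  grid <- g >= lo & g <= hi
  structure(list(grid = grid, area = sum(grid), peptide = peptide,
                 section_id = section_id),
            class = "BinaryMask")
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("BinaryMask '%s' section '%s': %d x %d px, area %d\n",
              x$peptide, x$section_id, nrow(x$grid), ncol(x$grid), x$area))
  invisible(x)
}

as_mask_stack <- function(stack) {
  if (inherits(stack, "BinaryMask")) stack <- list(stack)
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]),
                    function(k) binarize(stack[, , k] * 65535, 1, 65535))
  if (is.matrix(stack)) stack <- list(binarize(stack * 65535, 1, 65535))
  lapply(stack, function(s) {
    if (inherits(s, "BinaryMask")) s
    else if (is.matrix(s)) binarize((s != 0) * 65535, 1, 65535)
    else stop("mask stacks must be BinaryMask objects or logical matrices")
  })
}

#' Pooled-area colocalization of two mask stacks
#'
#' Foreground areas of the two section stacks and of their overlap are summed
#' over all sections before the ratios are taken (one coefficient per pair
#' for the whole stack, not a per-section mean):
#' Tanimoto = overlap / (areaA + areaB - overlap), M1 = overlap / areaA,
#' M2 = overlap / areaB. Two empty stacks give Tanimoto 0 by convention
#' ("not colocalized"); M1/M2 are `NA` when the corresponding area is 0.
#'
#' @param stack_a,stack_b section-aligned stacks: lists of `BinaryMask` (or
#'   logical matrices / 3D arrays) with matching section counts and shapes.
#' @param peptide_a,peptide_b names for the report (default from the masks).
#' @return object of class `ColocResult`: list with `peptide_a`, `peptide_b`,
#'   `area_a`, `area_b`, `area_overlap`, `tanimoto`, `m1`, `m2`.
#' @export
coloc_pair <- function(stack_a, stack_b, peptide_a = NULL, peptide_b = NULL) {
  a <- as_mask_stack(stack_a); b <- as_mask_stack(stack_b)
  if (length(a) != length(b))
    stop("section count mismatch between the two stacks")
  area_a <- 0; area_b <- 0; overlap <- 0
  for (k in seq_along(a)) {
    if (!identical(dim(a[[k]]$grid), dim(b[[k]]$grid)))
      stop(sprintf("section %d: mask shapes differ", k))
    area_a <- area_a + a[[k]]$area
    area_b <- area_b + b[[k]]$area
    overlap <- overlap + sum(a[[k]]$grid & b[[k]]$grid)
  }
  denom <- area_a + area_b - overlap
  structure(list(
    peptide_a = peptide_a %||% (if (length(a)) a[[1]]$peptide else NA),
    peptide_b = peptide_b %||% (if (length(b)) b[[1]]$peptide else NA),
    area_a = area_a, area_b = area_b, area_overlap = overlap,
    tanimoto = if (denom > 0) overlap / denom else 0,
    m1 = if (area_a > 0) overlap / area_a else NA_real_,
    m2 = if (area_b > 0) overlap / area_b else NA_real_),
    class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf(
    "ColocResult %s vs %s: A=%d B=%d overlap=%d  T=%.4f M1=%.4f M2=%.4f\n",
    x$peptide_a, x$peptide_b, x$area_a, x$area_b, x$area_overlap,
    x$tanimoto, x$m1, x$m2))
  invisible(x)
}

#' @rdname coloc_pair
#' @export
tanimoto <- function(stack_a, stack_b, peptide_a = NULL, peptide_b = NULL) {
  coloc_pair(stack_a, stack_b, peptide_a, peptide_b)
}

#' Manders coefficients of two mask stacks
#'
#' @inheritParams coloc_pair
#' @return named numeric `c(m1 = , m2 = )`; `NA` where the corresponding
#'   area is zero (undefined).
#' @export
manders <- function(stack_a, stack_b) {
  r <- coloc_pair(stack_a, stack_b)
  c(m1 = r$m1, m2 = r$m2)
}

#' Pairwise Tanimoto matrix over a set of peptide mask stacks
#'
#' @param stacks named list; each element is one peptide's section stack
#'   (list of `BinaryMask`). All stacks must cover the same sections.
#' @param precursor optional named character vector grouping peptides by
#'   precursor; when given, rows are ordered by precursor group (input order
#'   within groups).
#' @return list with `tanimoto` (symmetric matrix, diagonal 1 for non-empty
#'   peptides, `NA` for all-empty ones), `pairs` (data.frame of all
#'   `ColocResult` fields) and `order` (row order used).
#' @export
coloc_matrix <- function(stacks, precursor = NULL) {
  if (length(stacks) < 2L) stop("need at least two peptides")
  if (is.null(names(stacks)) || any(!nzchar(names(stacks))))
    stop("stacks must be a named list (peptide names)")
  ns <- vapply(stacks, length, 0L)
  if (length(unique(ns)) != 1L) stop("stacks cover different section sets")
  peps <- names(stacks)
  if (!is.null(precursor)) {
    grp <- precursor[peps]
    peps <- peps[order(match(grp, unique(grp)))]
    stacks <- stacks[peps]
  }
  n <- length(peps)
  mat <- matrix(NA_real_, n, n, dimnames = list(peps, peps))
  rows <- list()
  areas <- vapply(stacks, function(s)
    sum(vapply(as_mask_stack(s), function(m) m$area, 0)), 0)
  for (i in seq_len(n)) mat[i, i] <- if (areas[i] > 0) 1 else NA_real_
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- coloc_pair(stacks[[i]], stacks[[j]], peps[i], peps[j])
    mat[i, j] <- mat[j, i] <- r$tanimoto
    rows[[length(rows) + 1L]] <- data.frame(
      peptide_a = peps[i], peptide_b = peps[j], area_a = r$area_a,
      area_b = r$area_b, area_overlap = r$area_overlap,
      tanimoto = r$tanimoto, m1 = r$m1, m2 = r$m2)
  }
  list(tanimoto = mat, pairs = do.call(rbind, rows), order = peps)
}

#' Plot (and optionally save) a colocalization heatmap
#'
#' Renders the pairwise Tanimoto matrix in input order (no clustering) on a
#' 0..1 color scale, the conventional display for whole-ganglion peptide
#' colocalization.
#'
#' @param mat symmetric Tanimoto matrix from [coloc_matrix()].
#' @param file optional PNG path; plots to the active device when `NULL`.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_coloc_heatmap <- function(mat, file = NULL, ...) {
  breaks <- seq(0, 1, length.out = 101)
  args <- list(mat = mat, cluster_rows = FALSE, cluster_cols = FALSE,
               breaks = breaks, na_col = "grey85",
               color = grDevices::hcl.colors(100, "Inferno"), ...)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 760)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  p <- do.call(pheatmap::pheatmap, args)
  invisible(p)
}

#' Write pairwise colocalization results to CSV
#'
#' @param coloc result of [coloc_matrix()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_coloc_csv <- function(coloc, path) {
  utils::write.csv(coloc$pairs, path, row.names = FALSE)
  invisible(path)
}

#' Write a mask stack as a multi-page 1-bit-style TIFF
#'
#' @param stack list of `BinaryMask`.
#' @param path output TIFF.
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(stack, path) {
  stack <- as_mask_stack(stack)
  pages <- lapply(stack, function(m) (m$grid) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
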