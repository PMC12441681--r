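#' Rigid 2D transform between imaging frames
#'
#' Maps physical coordinates (micrometers, relative to the image center,
#' x rightwards, y downwards) of a moving frame into a fixed frame:
#' `p_fixed = R(theta) (scale * p_moving) + (dx, dy)`, where `R(theta)` is a
#' rotation by `theta` degrees counter-clockwise as displayed (top-left
#' origin, y down).
#'
#' @param dx,dy translation in micrometers.
#' @param theta rotation in degrees, counter-clockwise about the image
#'   center, in (-180, 180].
#' @param scale micron-per-micron zoom between frames (> 0); physical pixel
#'   sizes are handled separately by the images, so `scale` defaults to 1.
#' @return object of class `TransformSpec`.
#' @export
transform_spec <- function(dx = 0, dy = 0, theta = 0, scale = 1) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  if (theta <= -180 || theta > 180) stop("theta must lie in (-180, 180]")
  structure(list(dx = dx, dy = dy, theta = theta, scale = scale),
            class = "TransformSpec")
}

#' @export
print.TransformSpec <- function(x, ...) {
  cat(sprintf("TransformSpec dx=%.3g um, dy=%.3g um, theta=%.3g deg, scale=%.3g\n",
              x$dx, x$dy, x$theta, x$scale))
  invisible(x)
}

#' Invert a rigid transform
#' @param transform `TransformSpec`.
#' @return the inverse `TransformSpec`.
#' @export
invert_transform <- function(transform) {
  th <- -transform$theta * pi / 180  # visual-CCW rotation, y-down frame
  # forward: p' = R t p * s + d  =>  inverse: p = R(-t) (p' - d) / s
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  d <- -rot %*% c(transform$dx, transform$dy) / transform$scale
  theta_inv <- -transform$theta
  if (theta_inv <= -180) theta_inv <- theta_inv + 360
  transform_spec(dx = d[1], dy = d[2], theta = theta_inv,
                 scale = 1 / transform$scale)
}

#' Convert an image to 8 bit with percentile auto-contrast
#'
#' Linearly rescales the `[p_low, p_high]` percentile range to 0..255 with
#' clipping, emulating the "auto" brightness/contrast of common image
#' software. A constant image maps to all zeros.
#'
#' @param image `GrayImage` (any bit depth).
#' @param p_low,p_high percentiles in percent (defaults 0.35 / 99.65).
#' @return 8-bit `GrayImage`.
#' @export
to_8bit_autocontrast <- function(image, p_low = 0.35, p_high = 99.65) {
  stopifnot(inherits(image, "GrayImage"))
  g <- image$grid
  if (!length(g)) stop("empty image")
  q <- stats::quantile(g, c(p_low, p_high) / 100, names = FALSE)
  if (q[2] <= q[1])
    return(gray_image(matrix(0, nrow(g), ncol(g)), "8", image$pixel_size))
  out <- round(255 * (g - q[1]) / (q[2] - q[1]))
  out <- pmin(pmax(out, 0), 255)
  gray_image(out, "8", image$pixel_size)
}

# separable grayscale erosion/dilation along one dimension with a 1D
# structuring function s(u) (s <= 0, s(0) = 0), implemented with shifted
# matrices; `op` is pmin (erosion) or pmax (dilation).
morpho_1d <- function(g, shape, radius, op, sign, by_row) {
  acc <- g
  for (u in seq(-radius, radius)) {
    if (u == 0) next
    sh <- if (by_row) shift_matrix(g, u, 0, fill = sign * Inf)
          else shift_matrix(g, 0, u, fill = sign * Inf)
    acc <- op(acc, sh - sign * shape(abs(u)))
  }
  acc
}

#' Subtract a rolling-ball / sliding-paraboloid background
#'
#' The background is the grayscale opening of the image with a non-flat
#' structuring element of the given radius - a sliding paraboloid
#' (`z = -u^2 / (2 radius)`, separable, default) or a spherical ball cap -
#' and is subtracted from the image. The result is never negative.
#'
#' @param image `GrayImage`.
#' @param radius structuring element radius in pixels (>= 1, smaller than the
#'   image extent); default 25.
#' @param paraboloid use the sliding paraboloid (default) instead of the ball.
#' @return `GrayImage` of the same bit depth with the background (attribute
#'   `"background"`) removed.
#' @export
subtract_background <- function(image, radius = 25, paraboloid = TRUE) {
  stopifnot(inherits(image, "GrayImage"))
  g <- image$grid
  if (radius < 1) stop("radius must be >= 1")
  if (2 * radius + 1 > max(dim(g)))
    stop("radius larger than the image extent")
  r <- as.integer(radius)
  if (paraboloid) {
    shape <- function(u) -u^2 / (2 * radius)
    # erosion: min over u of f(x+u) - s(u); separable in x then y
    ero <- morpho_1d(g,   shape, r, pmin, +1, by_row = TRUE)
    ero <- morpho_1d(ero, shape, r, pmin, +1, by_row = FALSE)
    dil <- morpho_1d(ero, shape, r, pmax, -1, by_row = TRUE)
    bg  <- morpho_1d(dil, shape, r, pmax, -1, by_row = FALSE)
  } else {
    offs <- expand.grid(du = -r:r, dv = -r:r)
    offs <- offs[offs$du^2 + offs$dv^2 <= radius^2, ]
    h <- sqrt(radius^2 - offs$du^2 - offs$dv^2) - radius  # <= 0
    ero <- matrix(Inf, nrow(g), ncol(g))
    for (k in seq_len(nrow(offs)))
      ero <- pmin(ero, shift_matrix(g, offs$du[k], offs$dv[k], Inf) - h[k])
    bg <- matrix(-Inf, nrow(g), ncol(g))
    for (k in seq_len(nrow(offs)))
      bg <- pmax(bg, shift_matrix(ero, -offs$du[k], -offs$dv[k], -Inf) + h[k])
  }
  bg <- pmin(bg, g)  # opening never exceeds the image
  out <- gray_image(round_if_int(g - bg, image$bit_depth), image$bit_depth,
                    image$pixel_size)
  attr(out, "background") <- bg
  out
}

round_if_int <- function(g, bit_depth) {
  if (bit_depth %in% c("8", "16")) pmax(round(g), 0) else pmax(g, 0)
}

#' Resample an image through a rigid transform (bilinear interpolation)
#'
#' Each output pixel center is mapped through the inverse of `transform` into
#' the source frame and sampled bilinearly; samples outside the source are 0
#' and recorded in the `"valid"` attribute mask so downstream statistics can
#' exclude them. Coordinates are physical (micrometers about each image
#' center), so source and output may have different pixel sizes - this is how
#' 20-micron MSI pixels are placed on the 1-micron microscopy grid.
#'
#' @param image source `GrayImage`.
#' @param transform `TransformSpec` mapping the source frame into the output
#'   frame.
#' @param out_shape integer (rows, cols) of the output grid; defaults to the
#'   source shape.
#' @param out_pixel_size output pixel size in micrometers; defaults to the
#'   source pixel size.
#' @return float `GrayImage` with attribute `"valid"` (logical matrix).
#' @export
apply_rigid_transform <- function(image, transform, out_shape = NULL,
                                  out_pixel_size = NULL) {
  stopifnot(inherits(image, "GrayImage"), inherits(transform, "TransformSpec"))
  out_shape <- out_shape %||% dim(image$grid)
  out_pixel_size <- out_pixel_size %||% image$pixel_size
  nr <- out_shape[1]; nc <- out_shape[2]
  # physical coordinates of output pixel centers, relative to output center
  xs <- ((seq_len(nc)) - 0.5 - nc / 2) * out_pixel_size
  ys <- ((seq_len(nr)) - 0.5 - nr / 2) * out_pixel_size
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  # inverse map into the source frame
  t <- -transform$theta * pi / 180  # inverse rotation, visual CCW, y down
  Xs <- X - transform$dx; Ys <- Y - transform$dy
  Xm <- (cos(t) * Xs + sin(t) * Ys) / transform$scale
  Ym <- (-sin(t) * Xs + cos(t) * Ys) / transform$scale
  # source pixel coordinates (pixel-center convention)
  src_nr <- nrow(image$grid); src_nc <- ncol(image$grid)
  cols <- Xm / image$pixel_size + src_nc / 2 + 0.5
  rows <- Ym / image$pixel_size + src_nr / 2 + 0.5
  s <- bilinear_sample(image$grid, as.vector(rows), as.vector(cols), fill = 0)
  out <- gray_image(matrix(s$values, nr, nc), "float", out_pixel_size)
  attr(out, "valid") <- matrix(s$valid, nr, nc)
  out
}

ncc_score <- function(a, b, valid) {
  va <- a[valid]; vb <- b[valid]
  if (length(va) < 9 || stats::sd(va) == 0 || stats::sd(vb) == 0)
    return(-Inf)
  stats::cor(va, vb)
}

#' Estimate a rigid transform by normalized cross-correlation grid search
#'
#' Exhaustively evaluates every (dx, dy, theta) combination of the supplied
#' grids, scoring the bilinear resample of `moving` against `fixed` by the
#' Pearson correlation over the valid overlap, then optionally refines around
#' the best point with successively halved steps.
#'
#' @param moving,fixed `GrayImage`s on comparable physical frames.
#' @param dx,dy candidate translations in micrometers (non-empty numeric).
#' @param theta candidate rotations in degrees.
#' @param n_refine number of coarse-to-fine refinement rounds (0 = plain
#'   exhaustive search over the given grids).
#' @return `TransformSpec` with attributes `"score"` (best correlation) and
#'   `"grid_step"` (final search steps).
#' @export
estimate_transform <- function(moving, fixed, dx = seq(-10, 10, 2),
                               dy = seq(-10, 10, 2),
                               theta = seq(-10, 10, 2.5), n_refine = 0) {
  stopifnot(inherits(moving, "GrayImage"), inherits(fixed, "GrayImage"))
  if (!length(dx) || !length(dy) || !length(theta))
    stop("empty search range")
  steps <- c(dx = if (length(dx) > 1) min(diff(sort(unique(dx)))) else 0,
             dy = if (length(dy) > 1) min(diff(sort(unique(dy)))) else 0,
             theta = if (length(theta) > 1) min(diff(sort(unique(theta)))) else 0)
  search <- function(dxs, dys, thetas) {
    best <- list(score = -Inf)
    for (th in thetas) for (x in dxs) for (y in dys) {
      tr <- transform_spec(x, y, th)
      res <- apply_rigid_transform(moving, tr, dim(fixed$grid),
                                   fixed$pixel_size)
      sc <- ncc_score(res$grid, fixed$grid, attr(res, "valid"))
      if (sc > best$score) best <- list(score = sc, transform = tr)
    }
    best
  }
  best <- search(dx, dy, theta)
  for (lvl in seq_len(n_refine)) {
    steps <- steps / 2
    b <- best$transform
    dxs <- b$dx + steps["dx"] * (-2:2)
    dys <- b$dy + steps["dy"] * (-2:2)
    ths <- b$theta + steps["theta"] * (-2:2)
    cand <- search(dxs, dys, ths)
    if (cand$score > best$score) best <- cand
  }
  out <- best$transform
  attr(out, "score") <- best$score
  attr(out, "grid_step") <- steps
  out
}

#' Read / write per-section alignment files
#'
#' Alignment files map section ids to rigid-transform parameters. JSON is
#' used by default; YAML is accepted when the yaml package is installed.
#'
#' @param path JSON (or YAML) file of `section id -> {dx, dy, theta, scale}`.
#' @return named list of `TransformSpec`.
#' @export
read_alignment <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML alignment files")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(p)
    transform_spec(p$dx %||% 0, p$dy %||% 0, p$theta %||% 0, p$scale %||% 1))
}

#' @rdname read_alignment
#' @param transforms named list of `TransformSpec` (names = section ids).
#' @export
write_alignment <- function(transforms, path) {
  jsonlite::write_json(
    lapply(transforms, function(t)
      list(dx = t$dx, dy = t$dy, theta = t$theta, scale = t$scale)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
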