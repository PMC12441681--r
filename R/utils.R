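#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift a matrix by whole pixels, filling vacated entries
#'
#' @param m numeric matrix.
#' @param dr,dc row/column shift (positive = towards larger indices).
#' @param fill value used for entries shifted in from outside.
#' @return shifted matrix of the same shape.
#' @keywords internal
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) + dr
  src_c <- seq_len(nc) + dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  if (any(ok_r) && any(ok_c))
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Bilinear sampling of a matrix at fractional pixel positions
#'
#' Positions use the pixel-center convention: the center of `grid[r, c]` is at
#' row coordinate `r`, column coordinate `c`. Samples falling outside the
#' convex hull of pixel centers are returned as `fill` and flagged invalid.
#'
#' @param grid numeric matrix to sample.
#' @param rows,cols fractional row/column coordinates (equal length).
#' @param fill value for out-of-bounds samples.
#' @return list with `values` and logical `valid` of the same length.
#' @keywords internal
bilinear_sample <- function(grid, rows, cols, fill = 0) {
  nr <- nrow(grid); nc <- ncol(grid)
  valid <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  # clamp base indices so the gather stays in range (fractions then cover the
  # exact-boundary case, e.g. a sample on the last pixel center)
  r0c <- pmin(pmax(floor(rows), 1), max(nr - 1, 1))
  c0c <- pmin(pmax(floor(cols), 1), max(nc - 1, 1))
  fr <- rows - r0c; fc <- cols - c0c
  r1 <- pmin(r0c + 1, nr); c1 <- pmin(c0c + 1, nc)
  i00 <- cbind(r0c, c0c)
  i10 <- cbind(r1,  c0c)
  i01 <- cbind(r0c, c1)
  i11 <- cbind(r1,  c1)
  v <- (1 - fr) * (1 - fc) * grid[i00] +
       fr       * (1 - fc) * grid[i10] +
       (1 - fr) * fc       * grid[i01] +
       fr       * fc       * grid[i11]
  v[!valid] <- fill
  list(values = v, valid = valid)
}

#' Label connected foreground components of a binary image
#'
#' Two foreground pixels belong to the same component when they touch in the
#' chosen neighbourhood (8-connectivity by default, i.e. edges and corners).
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels, 0 = background, components numbered
#'   consecutively from 1 in scan order.
#' @export
label_connected <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    off <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1,  0,  1, -1, 1, -1, 0, 1))
  } else {
    off <- cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  fg <- which(mask)
  cur <- 0L
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    frontier <- start
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nbr_r <- rep(r, each = nrow(off)) + off[, "dr"]
      nbr_c <- rep(c, each = nrow(off)) + off[, "dc"]
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      idx <- unique((nbr_c[ok] - 1L) * nr + nbr_r[ok])
      idx <- idx[mask[idx] & lab[idx] == 0L]
      lab[idx] <- cur
      frontier <- idx
    }
  }
  lab
}

#' Derive a 31-bit seed from a base seed and integer salts
#' @keywords internal
derive_seed <- function(seed, ...) {
  salts <- c(...)
  x <- as.numeric(seed) %% 2147483629
  for (s in salts) x <- (x * 48271 + as.numeric(s) * 16807 + 1) %% 2147483629
  as.integer(x + 1)
}
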