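# Shared fixtures: random MSI datasets, smooth test images, binary masks and
# an independent intermodes oracle used to cross-check the implementation.

random_msi <- function(n_px = 6, n_peaks = 5, seed = 1) {
  set.seed(seed)
  side <- ceiling(sqrt(n_px))
  coords <- expand.grid(x = 0:(side - 1), y = 0:(side - 1))[seq_len(n_px), ]
  mz <- lapply(seq_len(n_px), function(i) sort(runif(n_peaks, 600, 4400)))
  intensity <- lapply(seq_len(n_px), function(i) runif(n_peaks, 0, 50))
  msi_dataset(coords, mz, intensity)
}

smooth_image <- function(n = 64, seed = 1, pixel_size = 1) {
  set.seed(seed)
  f1 <- runif(1, 4, 9); f2 <- runif(1, 5, 12)
  ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
  g <- outer(sin(seq_len(n) / f1 + ph1), cos(seq_len(n) / f2 + ph2)) +
    outer(seq_len(n) / n, seq_len(n) / n) + 2
  gray_image(g, "float", pixel_size)
}

block_mask <- function(nr = 10, nc = 10, rows = 2:4, cols = 2:4, ...) {
  m <- matrix(FALSE, nr, nc)
  m[rows, cols] <- TRUE
  binarize(m * 65535, 1, 65535, ...)
}

random_mask <- function(nr = 12, nc = 12, p = 0.4) {
  binarize(matrix(runif(nr * nc) < p, nr, nc) * 65535, 1, 65535)
}

# independent re-implementation of the intermodes rule: 256-level histogram,
# iterated 3-bin running mean until two strict local maxima survive, midpoint
# of the mode levels rescaled to 16 bit
oracle_intermodes <- function(values16, max_iter = 10000) {
  h <- tabulate(pmin(pmax(floor(values16 / 257), 0), 255) + 1L, 256)
  h <- as.numeric(h)
  count_modes <- function(x) {
    n <- length(x)
    which(x > c(-Inf, x[-n]) & x > c(x[-1], -Inf))
  }
  for (it in seq_len(max_iter + 1)) {
    m <- count_modes(h)
    if (length(m) <= 2) break
    h <- (c(0, h[-256]) + h + c(h[-1], 0)) / 3
  }
  m <- count_modes(h)
  if (length(m) != 2) stop("oracle: not bimodal")
  floor((m[1] - 1 + m[2] - 1) / 2) * 257
}

small_phantom_config <- function(seed = 1, n_sections = 2,
                                 cells_per_section = 8,
                                 semiaxes = c(x = 90, y = 70), ...) {
  phantom_config(seed = seed, n_sections = n_sections,
                 cells_per_section = cells_per_section,
                 semiaxes = semiaxes, ...)
}
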