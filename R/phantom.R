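# Synthetic ganglion phantoms: co-registered fluorescence microscopy and MSI
# datasets with known cells, regional peptide programs, transform and noise,
# used as ground truth for every pipeline stage.

#' Default synthetic peptide panel (6 channels)
#'
#' Six peptide channels with distinct target m/z inside the acquired range;
#' two ventral channels share a precursor and are co-expressed by default.
#' All values are synthetic conventions of the phantom, not measured masses.
#'
#' @return data.frame with `name`, `mz`, `precursor`, `mean_intensity`,
#'   `color`.
#' @export
default_peptide_panel <- function() {
  data.frame(
    name = c("pep-TK", "pep-CCK", "pep-NT", "pep-LFa", "pep-LFb", "pep-bcast"),
    mz = c(1424.72, 1042.48, 1528.75, 988.52, 1186.60, 2145.05),
    precursor = c("tk", "cck", "nt", "lf", "lf", "bcast"),
    mean_intensity = c(120, 100, 110, 90, 95, 80),
    color = c("red", "green", "blue", "magenta", "cyan", "yellow"),
    stringsAsFactors = FALSE)
}

PHANTOM_REGIONS <- c("dorso-rostral", "dorso-caudal", "ventral")

#' Default regional expression programs
#'
#' Per-region Bernoulli expression probabilities for each peptide channel,
#' emulating an oval ganglion divided into dorso-rostral, dorso-caudal and
#' ventral domains: one dorsal-wide channel, one rostral-only, one
#' caudal-only, a co-expressed ventral pair, and one broadly expressed
#' channel.
#'
#' @param peptides peptide panel data.frame (default panel when omitted).
#' @return matrix `[region, peptide]` of probabilities.
#' @export
default_region_programs <- function(peptides = default_peptide_panel()) {
  prob <- rbind(
    `dorso-rostral` = c(0.80, 0.80, 0.05, 0.05, 0.05, 0.50),
    `dorso-caudal`  = c(0.80, 0.05, 0.80, 0.05, 0.05, 0.50),
    `ventral`       = c(0.05, 0.05, 0.05, 0.80, 0.80, 0.50))
  if (ncol(prob) != nrow(peptides))
    stop("default programs are defined for 6 peptide channels")
  colnames(prob) <- peptides$name
  prob
}

#' Phantom configuration
#'
#' Defines a synthetic whole-ganglion phantom: an oval tissue sectioned into
#' `n_sections` serial slices whose outline tapers smoothly along z, filled
#' with non-overlapping round cells whose peptide content follows per-region
#' expression programs plus explicit co-expression couplings, rendered both
#' as 1-micrometer fluorescence microscopy and as a 20-micrometer MSI grid
#' related by a known rigid transform.
#'
#' @param seed integer; the single source of randomness for the phantom.
#' @param n_sections number of serial sections (default 36, section thickness
#'   10 micrometers).
#' @param cells_per_section cells placed in every section (default 50).
#' @param semiaxes tissue ellipse semi-axes (x, y) in micrometers.
#' @param diam_range cell diameter bounds in micrometers (default 5-14, the
#'   ganglion neuron size range); diameters are drawn 1 micrometer inside the
#'   bounds so the rendered soft-edged cells stay within them as measured.
#' @param px_micro,px_msi microscopy / MSI pixel size in micrometers.
#' @param margin_um blank margin around the tissue in the microscopy frame.
#' @param transform true rigid transform mapping the MSI frame onto the
#'   microscopy frame.
#' @param peptides peptide panel data.frame (`name`, `mz`, `precursor`,
#'   `mean_intensity`).
#' @param programs `[region, peptide]` probability matrix.
#' @param co_expression list of couplings `list(a=, b=, p=)`: with
#'   probability `p` the two channels share one expression draw in a cell.
#' @param noise list: `fluor_sd` (additive Gaussian sd, microscopy),
#'   `lognorm_sd` (per-cell lognormal intensity sd), `baseline_n` /
#'   `baseline_mean` (random baseline peaks per spectrum), `matrix_mz` /
#'   `matrix_intensity` (fixed matrix-cluster peaks present in every pixel).
#' @param peak_sd MSI Gaussian peak sd in Da (default 0.08).
#' @param cell_amplitude peak fluorescence of a cell (arbitrary units).
#' @param mz_range acquired mass range.
#' @param taper in-plane shrinkage of the outline at the first/last section
#'   (0.85 = end sections are 85 percent of the central outline).
#' @return object of class `PhantomConfig`.
#' @export
phantom_config <- function(seed = 1, n_sections = 36, cells_per_section = 50,
                           semiaxes = c(x = 260, y = 175),
                           diam_range = c(5, 14), px_micro = 1, px_msi = 20,
                           margin_um = 20,
                           transform = transform_spec(dx = 8, dy = -6, theta = 4),
                           peptides = default_peptide_panel(),
                           programs = default_region_programs(peptides),
                           co_expression = list(list(a = "pep-LFa",
                                                     b = "pep-LFb", p = 0.9)),
                           noise = list(fluor_sd = 3, lognorm_sd = 0.3,
                                        baseline_n = 400, baseline_mean = 7.5,
                                        matrix_mz = c(550.16, 568.14, 716.42),
                                        matrix_intensity = 15),
                           peak_sd = 0.08, cell_amplitude = 200,
                           mz_range = c(500, 4500), taper = 0.85) {
  stopifnot(diam_range[1] > 0, diam_range[2] > diam_range[1],
            px_msi >= px_micro, n_sections >= 1, cells_per_section >= 0,
            taper > 0, taper <= 1)
  if (any(peptides$mz < mz_range[1] | peptides$mz > mz_range[2]))
    stop("peptide m/z outside the acquired mass range")
  if (any(programs < 0 | programs > 1))
    stop("expression probabilities must lie in [0, 1]")
  if (diam_range[2] >= min(semiaxes))
    stop("cell diameters must fit inside the tissue")
  for (ce in co_expression)
    if (!all(c(ce$a, ce$b) %in% peptides$name) || ce$p < 0 || ce$p > 1)
      stop("co_expression entries need valid peptide names and p in [0, 1]")
  structure(list(seed = seed, n_sections = n_sections,
                 cells_per_section = cells_per_section, semiaxes = semiaxes,
                 diam_range = diam_range, px_micro = px_micro,
                 px_msi = px_msi, margin_um = margin_um,
                 transform = transform, peptides = peptides,
                 programs = programs, co_expression = co_expression,
                 noise = noise, peak_sd = peak_sd,
                 cell_amplitude = cell_amplitude, mz_range = mz_range,
                 taper = taper, section_thickness = 10),
            class = "PhantomConfig")
}

# outline shrink factor of section k (1-based); 1 at the center,
# `taper` at the two ends
section_scale <- function(config, k) {
  n <- config$n_sections
  u <- if (n == 1) 0 else 2 * (k - 1) / (n - 1) - 1
  sqrt(1 - (1 - config$taper^2) * u^2)
}

region_of <- function(x, y) {
  ifelse(y < 0, ifelse(x < 0, "dorso-rostral", "dorso-caudal"), "ventral")
}

#' Generate the ground truth of a phantom
#'
#' Places non-overlapping cells (centers at least one cell diameter plus a
#' 3-micrometer clearance apart) uniformly inside each section's ellipse,
#' assigns each cell a region by position and draws its peptide expression
#' from the region program, honoring the co-expression couplings. Fully
#' reproducible from the config seed.
#'
#' @param config `PhantomConfig`.
#' @return object of class `PhantomTruth`: list with `cells` (data.frame:
#'   `section`, `cell`, `x_um`, `y_um` centered tissue coordinates,
#'   `diameter_um`, `brightness`, `region`, and one `expr_<peptide>` level
#'   column per channel) and `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  set.seed(derive_seed(config$seed, 101))
  peps <- config$peptides$name
  coupled <- unlist(lapply(config$co_expression, function(ce) c(ce$a, ce$b)))
  rows <- vector("list", config$n_sections)
  for (k in seq_len(config$n_sections)) {
    s <- section_scale(config, k)
    a <- config$semiaxes[["x"]] * s
    b <- config$semiaxes[["y"]] * s
    n <- config$cells_per_section
    xs <- numeric(n); ys <- numeric(n); ds <- numeric(n)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 4000L * max(n, 1L)
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(paste0("cell packing failed in section %d: placed %d of",
                            " %d cells in %d attempts (tissue %.0f x %.0f um;",
                            " reduce cells_per_section or enlarge the tissue)"),
                     k, placed, n, attempts, 2 * a, 2 * b))
      d <- stats::runif(1, config$diam_range[1] + 1, config$diam_range[2] - 1)
      x <- stats::runif(1, -a, a); y <- stats::runif(1, -b, b)
      if ((x / (a - d / 2 - 1))^2 + (y / (b - d / 2 - 1))^2 > 1) next
      if (placed > 0L) {
        i <- seq_len(placed)
        mind <- pmax(ds[i], d) + 3
        if (any((xs[i] - x)^2 + (ys[i] - y)^2 < mind^2)) next
      }
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y; ds[placed] <- d
    }
    reg <- region_of(xs, ys)
    expr <- matrix(0, n, length(peps), dimnames = list(NULL, peps))
    for (i in seq_len(n)) {
      p_reg <- config$programs[reg[i], ]
      on <- stats::runif(length(peps)) < p_reg
      names(on) <- peps
      for (ce in config$co_expression) {
        if (stats::runif(1) < ce$p) {
          shared <- stats::runif(1) < mean(p_reg[c(ce$a, ce$b)])
          on[ce$a] <- shared; on[ce$b] <- shared
        }
      }
      lev <- config$peptides$mean_intensity *
        exp(stats::rnorm(length(peps), 0, config$noise$lognorm_sd))
      expr[i, ] <- ifelse(on, lev, 0)
    }
    rows[[k]] <- data.frame(section = rep(k, n), cell = seq_len(n), x_um = xs,
                            y_um = ys, diameter_um = ds,
                            brightness = stats::runif(n, 0.7, 1.3),
                            region = as.character(reg),
                            stringsAsFactors = FALSE)
    colnames(expr) <- paste0("expr_", peps)
    rows[[k]] <- cbind(rows[[k]], as.data.frame(expr))
  }
  structure(list(cells = do.call(rbind, rows), config = config),
            class = "PhantomTruth")
}

#' @export
print.PhantomTruth <- function(x, ...) {
  cat(sprintf("PhantomTruth: %d sections x %d cells, %d peptide channels, seed %s\n",
              x$config$n_sections, x$config$cells_per_section,
              nrow(x$config$peptides), format(x$config$seed)))
  invisible(x)
}

micro_shape <- function(config) {
  c(ny = 2 * ceiling((config$semiaxes[["y"]] + config$margin_um) / config$px_micro),
    nx = 2 * ceiling((config$semiaxes[["x"]] + config$margin_um) / config$px_micro))
}

#' Render the microscopy channels of one phantom section
#'
#' Fluorescence: every cell is a soft-edged disc (gently domed core of radius
#' d/2 - 0.5 micrometers so the maximum is unique at the centroid, Gaussian
#' edge of sd 0.5) scaled by the cell's brightness factor, on top of a faint
#' tissue autofluorescence and an illumination gradient, with additive
#' Gaussian noise. The DIC-like channel
#' carries the tissue outline only.
#'
#' @param truth `PhantomTruth`.
#' @param section section index.
#' @param noise render with additive noise (TRUE) or noise-free.
#' @return list with `fluor` and `dic`, both float `GrayImage`s on the
#'   microscopy grid.
#' @export
render_microscopy <- function(truth, section, noise = TRUE) {
  stopifnot(inherits(truth, "PhantomTruth"))
  config <- truth$config
  set.seed(derive_seed(config$seed, 202, section))
  shp <- micro_shape(config)
  ny <- shp[["ny"]]; nx <- shp[["nx"]]
  ps <- config$px_micro
  s <- section_scale(config, section)
  a <- config$semiaxes[["x"]] * s; b <- config$semiaxes[["y"]] * s
  xs <- ((seq_len(nx)) - 0.5 - nx / 2) * ps
  ys <- ((seq_len(ny)) - 0.5 - ny / 2) * ps
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  inside <- (X / a)^2 + (Y / b)^2 <= 1
  fluor <- 12 * inside + 6 * (X - min(xs)) / (2 * max(xs) + 1e-9)
  cells <- truth$cells[truth$cells$section == section, , drop = FALSE]
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x_um[i]; cy <- cells$y_um[i]; d <- cells$diameter_um[i]
    amp <- config$cell_amplitude * cells$brightness[i]
    r0 <- d / 2 - 0.5
    half <- ceiling((d / 2 + 2.5) / ps)
    cc <- round(cx / ps + nx / 2 + 0.5); rr <- round(cy / ps + ny / 2 + 0.5)
    rs <- max(1, rr - half):min(ny, rr + half)
    cs <- max(1, cc - half):min(nx, cc + half)
    dist <- sqrt(outer((ys[rs] - cy)^2, (xs[cs] - cx)^2, `+`))
    # gentle dome (5% center-to-edge) so the intensity maximum is unique at
    # the centroid; Gaussian soft edge of sd 0.5 um beyond the core
    core <- 1 - 0.05 * (dist / max(r0, 0.5))^2
    prof <- ifelse(dist <= r0, core,
                   0.95 * exp(-(dist - r0)^2 / (2 * 0.5^2)))
    fluor[rs, cs] <- fluor[rs, cs] + amp * prof
  }
  dic <- 80 * inside + 20 * ((X / a)^2 + (Y / b)^2 > 0.92 & inside)
  if (noise) {
    fluor <- fluor + stats::rnorm(length(fluor), 0, config$noise$fluor_sd)
    dic <- dic + stats::rnorm(length(dic), 0, config$noise$fluor_sd)
  }
  list(fluor = gray_image(pmax(fluor, 0), "float", ps),
       dic = gray_image(pmax(dic, 0), "float", ps))
}

msi_shape <- function(config) {
  shp <- micro_shape(config)
  half_x <- shp[["nx"]] / 2 * config$px_micro
  half_y <- shp[["ny"]] / 2 * config$px_micro
  # map the microscopy corners through the inverse transform to size the grid
  inv <- invert_transform(config$transform)
  corners <- rbind(c(-half_x, -half_y), c(half_x, -half_y),
                   c(-half_x, half_y), c(half_x, half_y))
  tt <- inv$theta * pi / 180
  out <- t(apply(corners, 1, function(q)
    c(cos(tt) * q[1] + sin(tt) * q[2],
      -sin(tt) * q[1] + cos(tt) * q[2]) * inv$scale + c(inv$dx, inv$dy)))
  c(ny = 2 * (ceiling(max(abs(out[, 2])) / config$px_msi) + 1),
    nx = 2 * (ceiling(max(abs(out[, 1])) / config$px_msi) + 1))
}

#' Render the MSI dataset of one phantom section
#'
#' Cell positions are mapped through the inverse of the true transform onto
#' the 20-micrometer MSI grid, and per-channel pixel intensities are chosen
#' so that bilinear (linear-interpolation) readback at every cell position
#' reproduces that cell's expression level - the transform-consistent forward
#' model (minimum-norm solution of the bilinear sampling system, clamped at
#' zero). Every expressed channel contributes a Gaussian peak (sd `peak_sd`)
#' at its target m/z sampled at 7 points; with `noise = TRUE` random baseline
#' peaks and fixed matrix-cluster peaks (which dominate the total ion count,
#' as matrix and chemical background do in real MALDI spectra) are added to
#' every pixel spectrum.
#'
#' @inheritParams render_microscopy
#' @return raw (non-normalized) `MSIDataset` covering the full MSI grid.
#' @export
render_msi <- function(truth, section, noise = TRUE) {
  stopifnot(inherits(truth, "PhantomTruth"))
  config <- truth$config
  set.seed(derive_seed(config$seed, 303, section))
  shp <- msi_shape(config)
  ny <- shp[["ny"]]; nx <- shp[["nx"]]
  ps <- config$px_msi
  peps <- config$peptides
  cells <- truth$cells[truth$cells$section == section, , drop = FALSE]
  tr <- config$transform
  t <- -tr$theta * pi / 180  # inverse rotation (micro -> MSI), y-down CCW
  channels <- array(0, c(ny, nx, nrow(peps)))
  if (nrow(cells) > 0) {
    # transform-consistent forward model: choose pixel values whose bilinear
    # readback at every cell position equals that cell's expression level
    # (minimum-norm solution of the sampling system, clamped at 0)
    A <- matrix(0, nrow(cells), ny * nx)
    for (i in seq_len(nrow(cells))) {
      xm <- cells$x_um[i] - tr$dx; ym <- cells$y_um[i] - tr$dy
      x_msi <- (cos(t) * xm + sin(t) * ym) / tr$scale
      y_msi <- (-sin(t) * xm + cos(t) * ym) / tr$scale
      colf <- x_msi / ps + nx / 2 + 0.5
      rowf <- y_msi / ps + ny / 2 + 0.5
      c0 <- floor(colf); r0 <- floor(rowf)
      fc <- colf - c0; fr <- rowf - r0
      w <- c((1 - fr) * (1 - fc), fr * (1 - fc), (1 - fr) * fc, fr * fc)
      rr <- c(r0, r0 + 1, r0, r0 + 1); cc <- c(c0, c0, c0 + 1, c0 + 1)
      ok <- rr >= 1 & rr <= ny & cc >= 1 & cc <= nx & w > 0
      A[i, (cc[ok] - 1) * ny + rr[ok]] <- w[ok]
    }
    lev_mat <- as.matrix(cells[, paste0("expr_", peps$name), drop = FALSE])
    gram <- A %*% t(A) + diag(1e-9, nrow(cells))
    V <- t(A) %*% solve(gram, lev_mat)
    V[V < 0] <- 0
    channels <- array(V, c(ny, nx, nrow(peps)))
  }
  offs <- (-3:3) * config$peak_sd
  w_peak <- stats::dnorm(offs, 0, config$peak_sd)
  w_peak <- w_peak / sum(w_peak)
  coords <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1))
  mz_list <- vector("list", nrow(coords))
  int_list <- vector("list", nrow(coords))
  lo <- config$mz_range[1]; hi <- config$mz_range[2]
  for (j in seq_len(nrow(coords))) {
    r <- coords$y[j] + 1L; c <- coords$x[j] + 1L
    mzv <- numeric(0); inv <- numeric(0)
    for (p in seq_len(nrow(peps))) {
      lev <- channels[r, c, p]
      if (lev <= 0) next
      mzv <- c(mzv, peps$mz[p] + offs)
      inv <- c(inv, lev * w_peak)
    }
    if (noise) {
      nb <- config$noise$baseline_n
      mzv <- c(mzv, stats::runif(nb, lo + 1, hi - 1), config$noise$matrix_mz)
      inv <- c(inv, stats::rexp(nb, 1 / config$noise$baseline_mean),
               config$noise$matrix_intensity *
                 stats::runif(length(config$noise$matrix_mz), 0.8, 1.2))
    }
    if (length(mzv)) {
      ord <- order(mzv)
      mzv <- mzv[ord]; inv <- inv[ord]
      dup <- c(FALSE, diff(mzv) == 0)
      if (any(dup)) {  # merge exact collisions to keep m/z strictly increasing
        grp <- cumsum(!dup)
        inv <- as.numeric(tapply(inv, grp, sum))
        mzv <- mzv[!dup]
      }
    }
    mz_list[[j]] <- mzv; int_list[[j]] <- inv
  }
  msi_dataset(coords, mz_list, int_list, pixel_size = ps,
              mz_range = config$mz_range, normalization = "raw")
}

#' Ground-truth cell masks of one peptide
#'
#' Rasterizes, per section, the cells expressing the peptide as hard discs of
#' their true diameter on the microscopy grid - the pipeline-free reference
#' masks used by [truth_coloc()].
#'
#' @param truth `PhantomTruth`.
#' @param peptide peptide name from the config panel.
#' @return list of `BinaryMask`, one per section.
#' @export
truth_masks <- function(truth, peptide) {
  config <- truth$config
  if (!peptide %in% config$peptides$name) stop("unknown peptide: ", peptide)
  shp <- micro_shape(config)
  ny <- shp[["ny"]]; nx <- shp[["nx"]]
  ps <- config$px_micro
  xs <- ((seq_len(nx)) - 0.5 - nx / 2) * ps
  ys <- ((seq_len(ny)) - 0.5 - ny / 2) * ps
  col <- paste0("expr_", peptide)
  lapply(seq_len(config$n_sections), function(k) {
    cells <- truth$cells[truth$cells$section == k & truth$cells[[col]] > 0, ,
                         drop = FALSE]
    m <- matrix(FALSE, ny, nx)
    for (i in seq_len(nrow(cells))) {
      cx <- cells$x_um[i]; cy <- cells$y_um[i]; r <- cells$diameter_um[i] / 2
      half <- ceiling(r / ps) + 1L
      cc <- round(cx / ps + nx / 2 + 0.5); rr <- round(cy / ps + ny / 2 + 0.5)
      rs <- max(1, rr - half):min(ny, rr + half)
      cs <- max(1, cc - half):min(nx, cc + half)
      dist2 <- outer((ys[rs] - cy)^2, (xs[cs] - cx)^2, `+`)
      m[rs, cs] <- m[rs, cs] | dist2 <= r^2
    }
    binarize(m * 65535, 1, 65535, peptide = peptide,
             section_id = as.character(k))
  })
}

#' Ground-truth Tanimoto coefficient of a peptide pair
#'
#' Computed directly from the truth table by rasterizing per-cell expression
#' indicators to masks and pooling areas over all sections - independent of
#' the imaging pipeline.
#'
#' @param truth `PhantomTruth`.
#' @param peptide_a,peptide_b channel names.
#' @return Tanimoto coefficient in [0, 1].
#' @export
truth_coloc <- function(truth, peptide_a, peptide_b) {
  coloc_pair(truth_masks(truth, peptide_a),
             truth_masks(truth, peptide_b))$tanimoto
}

#' Run the full imaging pipeline on a phantom
#'
#' For every section: render the fluorescence, convert to 8 bit with
#' auto-contrast, subtract the rolling-paraboloid background, segment cells;
#' render and TIC-normalize the MSI data, extract one ion image per peptide
#' (+/- 0.25 Da), integrate it onto the microscopy grid through the true
#' transform, promote to 16 bit and binarize with the fixed inclusive range.
#' The segmentation diameter bounds default to the config's cell-size range
#' widened by 1.5 micrometers for the soft-edge rendering halo.
#'
#' @param truth `PhantomTruth`.
#' @param noise render with noise (default TRUE).
#' @param d_min,d_max segmentation size filter in micrometers.
#' @param lo,hi binarization range on the 16-bit scale.
#' @param background_radius rolling-paraboloid radius in pixels.
#' @return list with `stacks` (named list: one mask stack per peptide),
#'   `mappings` (per-section lists of `MappingImage`), `n_cells` per section.
#' @export
run_phantom_pipeline <- function(truth, noise = TRUE,
                                 d_min = NULL, d_max = NULL,
                                 lo = 8400, hi = 65535,
                                 background_radius = 25) {
  stopifnot(inherits(truth, "PhantomTruth"))
  config <- truth$config
  d_min <- d_min %||% (config$diam_range[1] - 1.5)
  d_max <- d_max %||% (config$diam_range[2] + 1.5)
  peps <- config$peptides
  stacks <- lapply(seq_len(nrow(peps)), function(p) vector("list", config$n_sections))
  names(stacks) <- peps$name
  mappings <- vector("list", config$n_sections)
  n_cells <- integer(config$n_sections)
  for (k in seq_len(config$n_sections)) {
    fluor <- render_microscopy(truth, k, noise = noise)$fluor
    img8 <- to_8bit_autocontrast(fluor)
    bgs <- subtract_background(img8, radius = background_radius,
                               paraboloid = TRUE)
    cells <- segment_fluorescent_cells(bgs, d_min = d_min, d_max = d_max)
    n_cells[k] <- cells$n_cells
    msi <- tic_normalize(render_msi(truth, k, noise = noise))
    maps <- vector("list", nrow(peps))
    for (p in seq_len(nrow(peps))) {
      ion <- extract_ion_image(msi, peps$mz[p], tolerance = 0.25)
      m <- integrate_mapping(ion, config$transform, cells,
                             peptide = peps$name[p],
                             section_id = as.character(k))
      maps[[p]] <- m
      stacks[[peps$name[p]]][[k]] <- binarize(to_16bit(m), lo, hi,
                                              peptide = peps$name[p],
                                              section_id = as.character(k))
    }
    names(maps) <- peps$name
    mappings[[k]] <- maps
  }
  list(stacks = stacks, mappings = mappings, n_cells = n_cells)
}
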