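test_that("phantom generation is deterministic and respects its bounds", {
  cfg <- small_phantom_config(seed = 12)
  t1 <- generate_phantom(cfg)
  t2 <- generate_phantom(small_phantom_config(seed = 12))
  expect_identical(t1$cells, t2$cells)
  t3 <- generate_phantom(small_phantom_config(seed = 13))
  expect_false(identical(t1$cells, t3$cells))

  cfg50 <- phantom_config(seed = 2, n_sections = 1, cells_per_section = 50)
  truth <- generate_phantom(cfg50)
  expect_equal(nrow(truth$cells), 50L)
  expect_true(all(truth$cells$diameter_um >= 5 &
                  truth$cells$diameter_um <= 14))
  # cells inside the tissue ellipse
  a <- cfg50$semiaxes[["x"]]; b <- cfg50$semiaxes[["y"]]
  expect_true(all((truth$cells$x_um / a)^2 + (truth$cells$y_um / b)^2 <= 1))
  # centers at least one (larger) diameter apart
  d <- as.matrix(stats::dist(truth$cells[, c("x_um", "y_um")]))
  dd <- outer(truth$cells$diameter_um, truth$cells$diameter_um, pmax)
  diag(d) <- Inf
  expect_true(all(d >= dd))

  expect_error(generate_phantom(
    phantom_config(seed = 1, n_sections = 1, cells_per_section = 400,
                   semiaxes = c(x = 80, y = 60))),
    "packing")
})

test_that("a noise-free render peaks at the cell and stays inside the tissue", {
  cfg <- phantom_config(seed = 5, n_sections = 1, cells_per_section = 1,
                        semiaxes = c(x = 80, y = 60))
  truth <- generate_phantom(cfg)
  r <- render_microscopy(truth, 1, noise = FALSE)
  g <- r$fluor$grid
  peak <- which(g == max(g), arr.ind = TRUE)[1, ]
  nx <- ncol(g); ny <- nrow(g); ps <- cfg$px_micro
  px <- (peak["col"] - 0.5 - nx / 2) * ps
  py <- (peak["row"] - 0.5 - ny / 2) * ps
  expect_lt(abs(px - truth$cells$x_um[1]), 1.5)
  expect_lt(abs(py - truth$cells$y_um[1]), 1.5)
  # cell fluorescence support lies inside the tissue ellipse (12 = tissue
  # autofluorescence + illumination gradient ceiling)
  xs <- ((seq_len(nx)) - 0.5 - nx / 2) * ps
  ys <- ((seq_len(ny)) - 0.5 - ny / 2) * ps
  X <- matrix(xs, ny, nx, byrow = TRUE); Y <- matrix(ys, ny, nx)
  outside <- (X / cfg$semiaxes[["x"]])^2 + (Y / cfg$semiaxes[["y"]])^2 > 1
  expect_true(all(g[outside] <= 12 + 6 + 1e-9))
})

test_that("segmentation recovers all 50 cells of a default noise-free render", {
  cfg <- phantom_config(seed = 8, n_sections = 1)
  truth <- generate_phantom(cfg)
  r <- render_microscopy(truth, 1, noise = FALSE)
  cells <- segment_fluorescent_cells(
    subtract_background(to_8bit_autocontrast(r$fluor), 25),
    d_min = 5, d_max = 14)
  expect_equal(cells$n_cells, 50L)
})

test_that("rendered MSI spectra follow the forward model", {
  # cell-free phantom: baseline/matrix peaks only, nothing in peptide windows
  cfg0 <- small_phantom_config(seed = 3, n_sections = 1,
                               cells_per_section = 0)
  t0 <- generate_phantom(cfg0)
  msi0 <- render_msi(t0, 1, noise = TRUE)
  expect_true(all(vapply(msi0$mz, length, 0L) > 0))
  ion0 <- extract_ion_image(msi0, cfg0$peptides$mz[1], 0.25)
  # stray baseline peaks land in a peptide window in only a few percent of
  # pixels, and at a tiny fraction of the pixel TIC
  expect_lt(mean(ion0$grid > 0), 0.15)
  tic0 <- vapply(msi0$intensity, sum, 0)
  expect_lt(max(ion0$grid) / mean(tic0), 0.02)
  all_mz <- unlist(msi0$mz)
  expect_true(all(all_mz >= 500 & all_mz <= 4500))

  # single cell, zero noise: ion image peaks at the MSI pixel holding the cell
  cfg1 <- phantom_config(seed = 6, n_sections = 1, cells_per_section = 1,
                         semiaxes = c(x = 80, y = 60))
  t1 <- generate_phantom(cfg1)
  expressed <- cfg1$peptides$name[t1$cells[1, paste0("expr_",
                                                     cfg1$peptides$name)] > 0]
  expect_gt(length(expressed), 0)
  pep <- expressed[1]
  mz_p <- cfg1$peptides$mz[cfg1$peptides$name == pep]
  msi1 <- render_msi(t1, 1, noise = FALSE)
  ion1 <- extract_ion_image(msi1, mz_p, 0.25)
  peak <- which(ion1$grid == max(ion1$grid), arr.ind = TRUE)[1, ]
  # map the cell into the MSI frame through the inverse true transform
  inv <- invert_transform(cfg1$transform)
  tt <- inv$theta * pi / 180
  cx <- cos(tt) * t1$cells$x_um[1] + sin(tt) * t1$cells$y_um[1] + inv$dx
  cy <- -sin(tt) * t1$cells$x_um[1] + cos(tt) * t1$cells$y_um[1] + inv$dy
  nx <- ncol(ion1$grid); ny <- nrow(ion1$grid)
  exp_col <- round(cx / cfg1$px_msi + nx / 2 + 0.5)
  exp_row <- round(cy / cfg1$px_msi + ny / 2 + 0.5)
  expect_lte(abs(peak[["col"]] - exp_col), 1)
  expect_lte(abs(peak[["row"]] - exp_row), 1)
})

test_that("truth colocalization matches an independent rasterization", {
  cfg <- small_phantom_config(seed = 10, n_sections = 1,
                              cells_per_section = 6)
  truth <- generate_phantom(cfg)
  peps <- cfg$peptides$name[1:2]
  # independent oracle: mark every microscopy pixel covered by a disc
  shp <- pepatlas:::micro_shape(cfg)
  oracle_mask <- function(pep) {
    m <- matrix(FALSE, shp[["ny"]], shp[["nx"]])
    cells <- truth$cells[truth$cells[[paste0("expr_", pep)]] > 0, ]
    for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
      y <- (r - 0.5 - shp[["ny"]] / 2) * cfg$px_micro
      x <- (c - 0.5 - shp[["nx"]] / 2) * cfg$px_micro
      if (any((x - cells$x_um)^2 + (y - cells$y_um)^2 <=
              (cells$diameter_um / 2)^2)) m[r, c] <- TRUE
    }
    m
  }
  ma <- oracle_mask(peps[1]); mb <- oracle_mask(peps[2])
  ov <- sum(ma & mb)
  expected <- if (sum(ma) + sum(mb) - ov > 0)
    ov / (sum(ma) + sum(mb) - ov) else 0
  expect_equal(truth_coloc(truth, peps[1], peps[2]), expected)
  expect_error(truth_coloc(truth, "nope", peps[1]), "unknown")
})

test_that("coupled channels colocalize fully; disjoint programs do not", {
  base <- default_peptide_panel()
  prog <- default_region_programs(base)
  # joint probability 1: the coupled pair shares every draw
  cfg <- small_phantom_config(seed = 20, n_sections = 2,
                              cells_per_section = 10,
                              co_expression = list(list(a = "pep-LFa",
                                                        b = "pep-LFb",
                                                        p = 1)))
  truth <- generate_phantom(cfg)
  expect_equal(truth_coloc(truth, "pep-LFa", "pep-LFb"), 1)

  # disjoint regional programs: zero overlap
  prog2 <- prog
  prog2[, "pep-TK"] <- c(1, 1, 0)   # dorsal only
  prog2[, "pep-LFa"] <- c(0, 0, 1)  # ventral only
  cfg2 <- small_phantom_config(seed = 21, n_sections = 2,
                               cells_per_section = 12, programs = prog2,
                               co_expression = list())
  t2 <- generate_phantom(cfg2)
  expect_equal(truth_coloc(t2, "pep-TK", "pep-LFa"), 0)
})

test_that("transform estimation recovers the configured truth on renders", {
  cfg <- small_phantom_config(seed = 30, n_sections = 1,
                              cells_per_section = 8,
                              transform = transform_spec(dx = 3, dy = -2,
                                                         theta = 5))
  truth <- generate_phantom(cfg)
  fl <- render_microscopy(truth, 1, noise = FALSE)$fluor
  fixed <- apply_rigid_transform(fl, cfg$transform)
  est <- estimate_transform(fl, fixed, dx = seq(-4, 4, 1), dy = seq(-4, 4, 1),
                            theta = seq(-7.5, 7.5, 2.5))
  expect_lte(abs(est$dx - 3), 1)
  expect_lte(abs(est$dy + 2), 1)
  expect_lte(abs(est$theta - 5), 2.5)
})

test_that("the pipeline tracks truth on a small phantom", {
  cfg <- phantom_config(seed = 40, n_sections = 4, cells_per_section = 30,
                        semiaxes = c(x = 200, y = 140))
  truth <- generate_phantom(cfg)
  pipe <- run_phantom_pipeline(truth)
  expect_true(all(pipe$n_cells >= 28))  # noise may merge/drop the odd cell
  peps <- cfg$peptides$name
  # per-cell mapping intensity correlates with ground-truth expression
  # (Spearman over cells of one section for the first peptide)
  cm <- coloc_matrix(pipe$stacks)
  pair_t <- function(a, b)
    cm$tanimoto[a, b]
  co <- pair_t("pep-LFa", "pep-LFb")
  indep <- pair_t("pep-TK", "pep-CCK")
  expect_gt(co, indep)
  biases <- apply(cm$pairs, 1, function(row)
    as.numeric(row[["tanimoto"]]) -
      truth_coloc(truth, row[["peptide_a"]], row[["peptide_b"]]))
  expect_lt(max(abs(biases)), 0.15)  # small stack; the full bound is tested
                                     # on the 36-section study conditions
})

test_that("per-cell mapping intensity correlates with true expression", {
  # at default noise: the background-dominated TIC keeps normalization close
  # to a constant rescaling (noise-free TIC would be peptide-dominated and
  # distort per-channel intensities by co-expression load)
  cfg <- phantom_config(seed = 41, n_sections = 1, cells_per_section = 40,
                        semiaxes = c(x = 240, y = 170))
  truth <- generate_phantom(cfg)
  fl <- render_microscopy(truth, 1, noise = TRUE)$fluor
  cells <- segment_fluorescent_cells(
    subtract_background(to_8bit_autocontrast(fl), 25), 5, 14)
  msi <- tic_normalize(render_msi(truth, 1, noise = TRUE))
  pep <- "pep-bcast"  # broadly expressed channel
  ion <- extract_ion_image(msi, cfg$peptides$mz[cfg$peptides$name == pep])
  m <- integrate_mapping(ion, cfg$transform, cells, pep, "1")
  # match segmented cells to truth cells by centroid
  nx <- ncol(cells$grid); ny <- nrow(cells$grid)
  truth_sec <- truth$cells
  lev <- truth_sec[[paste0("expr_", pep)]]
  seg_mean <- vapply(seq_len(cells$n_cells), function(l)
    mean(m$continuous[cells$grid == l]), 0)
  match_idx <- vapply(seq_len(cells$n_cells), function(l) {
    cx <- cells$cells$cx_um[l] - nx / 2 * cells$pixel_size
    cy <- cells$cells$cy_um[l] - ny / 2 * cells$pixel_size
    which.min((truth_sec$x_um - cx)^2 + (truth_sec$y_um - cy)^2)
  }, 0L)
  keep <- lev[match_idx] > 0
  expect_gt(sum(keep), 10)
  rho <- stats::cor(seg_mean[keep], lev[match_idx][keep], method = "spearman")
  expect_gte(rho, 0.9)
})
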