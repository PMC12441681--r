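make_blob_image <- function(centers, radius_px = 4, n = 80, value = 200) {
  g <- matrix(0, n, n)
  for (k in seq_len(nrow(centers))) {
    for (r in seq_len(n)) for (c in seq_len(n)) {
      if ((r - centers[k, 1])^2 + (c - centers[k, 2])^2 <= radius_px^2)
        g[r, c] <- value
    }
  }
  gray_image(g, "8", 1)
}

test_that("cell segmentation thresholds, labels 8-connected and size-filters", {
  img <- make_blob_image(rbind(c(20, 20), c(60, 60)), radius_px = 4)
  cells <- segment_fluorescent_cells(img, 5, 14)
  expect_equal(cells$n_cells, 2L)
  expect_setequal(unique(as.vector(cells$grid)), c(0L, 1L, 2L))
  expect_equal(sort(cells$cells$cx_um), c(19.5, 59.5), tolerance = 0.02)
  # equivalent diameter of an r=4 px rasterized disc is ~8.1 um at 1 um/px
  expect_true(all(cells$cells$diameter_um > 7 & cells$cells$diameter_um < 9))

  blank <- gray_image(matrix(0, 40, 40), "8", 1)
  expect_equal(segment_fluorescent_cells(blank)$n_cells, 0L)

  # a 1-pixel blob at 1 um/px has equivalent diameter ~1.1 um < 5 um
  tiny <- matrix(0, 40, 40); tiny[20, 20] <- 255
  expect_equal(segment_fluorescent_cells(gray_image(tiny, "8", 1))$n_cells, 0L)

  expect_error(
    segment_fluorescent_cells(gray_image(matrix(0.5, 5, 5), "float", 1)),
    "8-bit")
})

test_that("labeling connectivity matches the 8-neighborhood", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal touch
  expect_equal(max(label_connected(m, 8)), 1L)
  expect_equal(max(label_connected(m, 4)), 2L)
})

test_that("integration masks the resampled ion image to cells and scales to 8 bit", {
  # full-frame single "cell" + constant ion image -> mask at 255
  lab <- matrix(1L, 40, 40)
  cells <- structure(list(grid = lab, n_cells = 1L,
                          cells = data.frame(label = 1L, area_px = 1600,
                                             cx_um = 20, cy_um = 20,
                                             diameter_um = 10),
                          pixel_size = 1, threshold = 0),
                     class = "CellLabelMap")
  # 4x4 MSI grid (80x80 um) so its pixel-center hull covers the whole
  # 40x40 um microscopy frame
  ion <- structure(list(grid = matrix(1, 4, 4), mask = matrix(TRUE, 4, 4),
                        target_mz = 1000, tolerance = 0.25,
                        max_intensity = 1, normalization = "TIC",
                        pixel_size = 20),
                   class = "IonImage")
  m <- integrate_mapping(ion, transform_spec(), cells, "pep", "s1")
  expect_true(all(m$grid == 255))

  zero_ion <- ion; zero_ion$grid <- matrix(0, 4, 4); zero_ion$max_intensity <- 0
  mz <- integrate_mapping(zero_ion, transform_spec(), cells)
  expect_true(all(mz$grid == 0))
  expect_true(attr(mz, "empty"))

  # half-masked grid: support stays inside the mask, interior values match
  # the unmasked resample
  lab2 <- lab; lab2[, 21:40] <- 0L
  cells2 <- cells; cells2$grid <- lab2
  set.seed(3)
  ion2 <- ion; ion2$grid <- matrix(runif(4, 1, 5), 2, 2)
  m2 <- integrate_mapping(ion2, transform_spec(), cells2)
  expect_true(all(m2$grid[, 21:40] == 0))
  src <- gray_image(ion2$grid, "float", 20)
  full <- apply_rigid_transform(src, transform_spec(), c(40, 40), 1)
  expect_equal(m2$continuous[, 1:20], full$grid[, 1:20])
})

test_that("integration support never exceeds the mask and scales monotonely", {
  set.seed(9)
  for (rep in 1:4) {
    lab <- matrix(0L, 30, 30)
    lab[sample(900, 200)] <- 1L
    cells <- structure(list(grid = lab, n_cells = 1L,
                            cells = data.frame(), pixel_size = 1,
                            threshold = 0),
                       class = "CellLabelMap")
    g <- matrix(runif(9, 0, 10), 3, 3)
    ion <- structure(list(grid = g, mask = matrix(TRUE, 3, 3),
                          target_mz = 900, tolerance = 0.25,
                          max_intensity = max(g), normalization = "TIC",
                          pixel_size = 10),
                     class = "IonImage")
    tr <- transform_spec(dx = runif(1, -3, 3), dy = runif(1, -3, 3),
                         theta = runif(1, -15, 15))
    m <- integrate_mapping(ion, tr, cells)
    expect_true(all(m$grid[lab == 0L] == 0))
    ion3 <- ion; ion3$grid <- 3 * g; ion3$max_intensity <- max(3 * g)
    m3 <- integrate_mapping(ion3, tr, cells)
    expect_equal(m3$continuous, 3 * m$continuous)
  }
})

test_that("composite rendering blends pseudocolors additively", {
  mk <- function(grid) structure(list(grid = grid, peptide = "p",
                                      section_id = "1", scale_max = 1,
                                      pixel_size = 1),
                                 class = "MappingImage")
  a <- matrix(0L, 10, 10); a[2:4, 2:4] <- 255L
  b <- matrix(0L, 10, 10); b[6:8, 6:8] <- 255L
  red <- mk(a); red$peptide <- "A"
  green <- mk(b); green$peptide <- "B"
  comp <- render_composite(list(red, green), c("red", "green"))
  expect_equal(comp[3, 3, ], c(255L, 0L, 0L))
  expect_equal(comp[7, 7, ], c(0L, 255L, 0L))
  expect_true(all(!(comp[, , 1] == 255 & comp[, , 2] == 255)))  # no yellow

  overlap <- render_composite(list(mk(a), mk(a)), c("red", "green"))
  expect_equal(overlap[3, 3, ], c(255L, 255L, 0L))  # saturated yellow

  small <- mk(matrix(0L, 5, 5))
  expect_error(render_composite(list(red, small), c("red", "green")),
               "shapes")
})

test_that("layer stacks round-trip pixels and page names", {
  mk <- function(name, fill) {
    g <- matrix(0L, 12, 12); g[3:6, 3:6] <- fill
    structure(list(grid = g, peptide = name, section_id = "1",
                   scale_max = 1, pixel_size = 1),
              class = "MappingImage")
  }
  maps <- list(mk("pepA", 200L), mk("pepB", 90L), mk("pepC", 17L))
  f <- tempfile(fileext = ".tif")
  export_layer_stack(maps, f)
  back <- read_layer_stack(f)
  expect_equal(names(back), c("pepA", "pepB", "pepC"))
  for (i in 1:3) expect_equal(back[[i]], maps[[i]]$grid)
  expect_error(export_layer_stack(list(), f), "no mapping")
  expect_error(export_layer_stack(list(mk("x", 1L), mk("x", 2L)), f),
               "duplicate")
})
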