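test_that("8-to-16-bit promotion maps the range endpoints by x257", {
  mk <- function(v) gray_image(matrix(v, 2, 2), "8", 1)
  expect_equal(to_16bit(mk(255))$grid[1, 1], 65535)
  expect_equal(to_16bit(mk(0))$grid[1, 1], 0)
  expect_equal(to_16bit(mk(33))$grid[1, 1], 8481)  # just above 8400
  expect_error(to_16bit(gray_image(matrix(0.1, 2, 2), "float", 1)), "8-bit")
})

test_that("intermodes thresholding matches the smoothing definition", {
  spikes <- matrix(c(rep(50, 60), rep(150, 60)) * 257, 12)
  expect_equal(threshold_intermodes(spikes), 100 * 257)
  spikes2 <- matrix(c(rep(10, 500), rep(20, 500)) * 257, 10)
  expect_equal(threshold_intermodes(spikes2), 15 * 257)
  expect_error(threshold_intermodes(matrix(7 * 257, 5, 5)), "unimodal")
})

test_that("intermodes equals an independent brute-force oracle", {
  set.seed(42)
  done <- 0
  while (done < 25) {
    n <- 3000
    mu <- sort(sample(20:235, 2))
    if (diff(mu) < 30) next
    v <- c(rnorm(n, mu[1], runif(1, 2, 8)), rnorm(n, mu[2], runif(1, 2, 8)))
    v16 <- pmin(pmax(round(v), 0), 255) * 257
    th <- tryCatch(threshold_intermodes(matrix(v16, 100)),
                   error = function(e) NULL)
    or <- tryCatch(oracle_intermodes(v16), error = function(e) NULL)
    expect_identical(th, or,
                     info = sprintf("modes %d/%d", mu[1], mu[2]))
    if (is.null(th) && is.null(or)) next  # never became bimodal; not counted
    done <- done + 1
  }
})

test_that("fixed-range binarization is inclusive at both bounds", {
  img <- matrix(c(8399, 8400, 65535, 0), 2, 2)
  m <- binarize(img, 8400, 65535)
  expect_equal(m$grid, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_equal(m$area, 2L)
  expect_equal(binarize(matrix(100, 3, 3), 8400, 65535)$area, 0L)
  expect_error(binarize(img, 10, 5), "lo")
  # idempotence: re-binarizing a mask rendered to 16 bit changes nothing
  r <- binarize(m$grid * 65535, 8400, 65535)
  expect_equal(r$grid, m$grid)
})

test_that("pooled-area Tanimoto and Manders follow the printed formulas", {
  a <- block_mask(rows = 2:4, cols = 2:4)
  expect_equal(coloc_pair(list(a, a, a), list(a, a, a))$tanimoto, 1)

  left <- block_mask(rows = 2:9, cols = 1:4)
  right <- block_mask(rows = 2:9, cols = 6:9)
  expect_equal(coloc_pair(list(left), list(right))$tanimoto, 0)

  # areas 100 and 100 with overlap 50 -> 50/150
  a100 <- block_mask(20, 20, rows = 1:10, cols = 1:10)   # 100 px
  b100 <- block_mask(20, 20, rows = 6:15, cols = 1:10)   # 100 px, overlap 50
  r <- coloc_pair(list(a100), list(b100))
  expect_equal(r$area_a, 100); expect_equal(r$area_b, 100)
  expect_equal(r$area_overlap, 50)
  expect_equal(r$tanimoto, 50 / 150)

  # areas 100 and 200 with overlap 50 -> M1 = 0.5, M2 = 0.25
  b200 <- block_mask(20, 20, rows = 6:15, cols = 1:20)
  m <- manders(list(a100), list(b200))
  expect_equal(unname(m["m1"]), 0.5)
  expect_equal(unname(m["m2"]), 0.25)

  # containment: A inside B gives M1 = 1
  sub <- block_mask(20, 20, rows = 7:9, cols = 2:4)
  expect_equal(unname(manders(list(sub), list(b200))["m1"]), 1)
  expect_equal(unname(manders(list(left), list(right))), c(0, 0))

  # both-empty convention and undefined Manders
  e <- block_mask(rows = integer(0), cols = integer(0))
  re <- coloc_pair(list(e), list(e))
  expect_equal(re$tanimoto, 0)
  expect_true(is.na(re$m1) && is.na(re$m2))

  expect_error(coloc_pair(list(a, a), list(a)), "section count")
  expect_error(coloc_pair(list(a), list(block_mask(5, 5, 1:2, 1:2))),
               "shapes")
})

test_that("1/T = 1/M1 + 1/M2 - 1 on random mask pairs with positive areas", {
  set.seed(99)
  checked <- 0
  while (checked < 200) {
    a <- random_mask(); b <- random_mask()
    r <- coloc_pair(list(a), list(b))
    if (r$area_overlap == 0 || r$area_a == 0 || r$area_b == 0) next
    expect_equal(1 / r$tanimoto, 1 / r$m1 + 1 / r$m2 - 1, tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("Tanimoto is symmetric and invariant to section order", {
  set.seed(5)
  sa <- lapply(1:4, function(i) random_mask())
  sb <- lapply(1:4, function(i) random_mask())
  r1 <- coloc_pair(sa, sb); r2 <- coloc_pair(sb, sa)
  expect_equal(r1$tanimoto, r2$tanimoto)
  perm <- c(3, 1, 4, 2)
  r3 <- coloc_pair(sa[perm], sb[perm])
  expect_equal(r1$tanimoto, r3$tanimoto)
  expect_equal(r1$area_overlap, r3$area_overlap)
})

test_that("pooling per-section areas equals counting on the stacked volume", {
  set.seed(13)
  sa <- lapply(1:3, function(i) random_mask(8, 8))
  sb <- lapply(1:3, function(i) random_mask(8, 8))
  r <- coloc_pair(sa, sb)
  cube_a <- array(unlist(lapply(sa, function(m) m$grid)), c(8, 8, 3))
  cube_b <- array(unlist(lapply(sb, function(m) m$grid)), c(8, 8, 3))
  ov <- sum(cube_a & cube_b)
  expect_equal(r$area_a, sum(cube_a))
  expect_equal(r$area_b, sum(cube_b))
  expect_equal(r$area_overlap, ov)
  expect_equal(r$tanimoto, ov / (sum(cube_a) + sum(cube_b) - ov))
})

test_that("the colocalization matrix is symmetric with a unit diagonal", {
  set.seed(21)
  stacks <- list(p1 = lapply(1:3, function(i) random_mask()),
                 p2 = lapply(1:3, function(i) random_mask()),
                 p3 = lapply(1:3, function(i) random_mask(p = 0)))
  cm <- coloc_matrix(stacks)
  expect_equal(cm$tanimoto, t(cm$tanimoto))
  expect_equal(cm$tanimoto["p1", "p1"], 1)
  expect_true(is.na(cm$tanimoto["p3", "p3"]))  # all-empty stack
  expect_equal(cm$tanimoto["p1", "p2"],
               coloc_pair(stacks$p1, stacks$p2)$tanimoto)
  two <- coloc_matrix(stacks[1:2])
  expect_equal(dim(two$tanimoto), c(2L, 2L))
  expect_equal(diag(two$tanimoto), c(p1 = 1, p2 = 1))
  expect_error(coloc_matrix(stacks[1]), "at least two")

  csv <- tempfile(fileext = ".csv")
  write_coloc_csv(cm, csv)
  expect_equal(nrow(utils::read.csv(csv)), 3L)

  f <- tempfile(fileext = ".png")
  plot_coloc_heatmap(cm$tanimoto, file = f)
  expect_true(file.size(f) > 0)
})
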