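test_that("Moran's I equals the brute-force double-sum oracle on small masks", {
  set.seed(10)
  for (r in 1:25) {
    ny <- sample(4:12, 1); nx <- sample(4:12, 1)
    mask <- matrix(runif(ny * nx) < 0.8, ny, nx)
    if (sum(mask) < 10) next
    vals <- matrix(rnorm(ny * nx), ny, nx)
    expect_equal(morans_I(vals, mask)$I, brute_moran(vals, mask),
                 tolerance = 1e-12)
  }
})

test_that("Moran's I reference patterns behave as expected", {
  # strict checkerboard on a full 8x8 mask: equals the oracle exactly
  cb <- (row(matrix(0, 8, 8)) + col(matrix(0, 8, 8))) %% 2
  full <- matrix(TRUE, 8, 8)
  expect_equal(morans_I(cb * 1.0, full)$I, brute_moran(cb * 1.0, full),
               tolerance = 1e-12)
  # smooth large-scale gradient: strongly positive autocorrelation
  g <- outer(1:32, 1:32, `+`) * 1.0
  expect_gt(morans_I(g, matrix(TRUE, 32, 32))$I, 0.5)
})

test_that("Moran's I agrees with an independent library on the same weights", {
  set.seed(13)
  mask <- matrix(TRUE, 9, 9)
  vals <- matrix(rnorm(81), 9, 9)
  w <- knn_weights(mask, 8)
  n <- nrow(w$coords)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, w$neighbors[i, ]] <- 1 / w$k
  expect_equal(morans_I(vals, mask)$I,
               ape::Moran.I(vals[w$coords], W)$observed, tolerance = 1e-12)
})

test_that("Moran's I is invariant under affine value transforms", {
  set.seed(11)
  mask <- cryoraman:::disk_mask(15, 15, 8, 8, 6)
  vals <- matrix(rnorm(225), 15, 15)
  i0 <- morans_I(vals, mask)$I
  expect_equal(morans_I(vals * -3.7 + 42, mask)$I, i0, tolerance = 1e-12)
})

test_that("i.i.d. fields sit at the permutation null", {
  set.seed(12)
  mask <- matrix(TRUE, 10, 10)
  inside3 <- vapply(1:100, function(i) {
    r <- morans_I(matrix(rnorm(100), 10, 10), mask)
    abs(r$z) <= 3
  }, logical(1))
  expect_gte(mean(inside3), 0.97)
})

test_that("Moran's I rejects degenerate inputs with informative failures", {
  mask <- matrix(TRUE, 6, 6)
  expect_error(morans_I(matrix(1, 6, 6), mask), "all equal")
  tiny <- matrix(FALSE, 6, 6); tiny[1:2, 1:2] <- TRUE
  expect_error(morans_I(matrix(rnorm(36), 6, 6), tiny), "at least k \\+ 2")
})

test_that("spatial weights are row-standardized 8-NN with no self-neighbours", {
  mask <- cryoraman:::disk_mask(12, 12, 6.5, 6.5, 5)
  w <- knn_weights(mask, 8)
  n <- nrow(w$coords)
  expect_equal(ncol(w$neighbors), 8)
  expect_false(any(w$neighbors == row(w$neighbors)))
  # row weights sum to one by construction (1/k each)
  expect_equal(w$k, 8)
})

test_that("ice metrics handle the trivial and phantom cases", {
  cell <- cryoraman:::disk_mask(40, 40, 20.5, 20.5, 15)
  seg0 <- cell_segmentation(cell, NULL, 0.333)
  m0 <- ice_metrics(NULL, seg0)
  expect_equal(m0$ice_area_fraction, 0)
  expect_false(m0$chunky)

  seg1 <- cell_segmentation(cell, cell, 0.333)
  m1 <- ice_metrics(NULL, seg1)
  expect_equal(m1$ice_area_fraction, 1)
  expect_true(m1$chunky)

  expect_error(ice_metrics(NULL, cell_segmentation(cell & FALSE, NULL, 1)),
               "empty cell mask")

  ph <- make_raman_phantom(cell_phantom_spec(ice_fraction = 0.3,
                                             chunky = FALSE, seed = 21),
                           bands = test_bands())
  row <- analyze_raman_cube(ph$cube, bands = test_bands())
  expect_lt(abs(row$ice_area_fraction - ph$truth$ice_fraction), 0.05)
  expect_false(row$chunky)
})

test_that("partition ratio has exact trivial limits and guarded arithmetic", {
  cell <- cryoraman:::disk_mask(40, 40, 20.5, 20.5, 12)
  seg <- cell_segmentation(cell, NULL, 0.333)
  uni <- heat_map(matrix(7, 40, 40), "glycerol", 0.333)
  expect_equal(partition_ratio(uni, seg), 1)

  # solute absent inside, positive floor outside: large but finite
  v <- matrix(5, 40, 40); v[cell] <- 0
  zin <- heat_map(v, "glycerol", 0.333)
  expect_error(partition_ratio(zin, seg), "not positive")
  r <- partition_ratio(zin, seg, floor = 1e-6)
  expect_true(is.finite(r) && r > 1e5)
})

test_that("partition ratio and hydration ratio are gain invariant", {
  ph <- make_raman_phantom(cell_phantom_spec(noise_level = 0, seed = 22),
                           bands = test_bands())
  seg <- ph$truth$segmentation
  sol <- integrate_band(ph$cube, band_window("glycerol"))
  r1 <- partition_ratio(sol, seg)
  sol2 <- heat_map(sol$values * 13, "glycerol", sol$pixel_pitch)
  expect_equal(partition_ratio(sol2, seg), r1, tolerance = 1e-12)

  c1 <- ch_oh_ratio(ph$cube, seg)
  cube2 <- raman_cube(ph$cube$intensities * 3.5, ph$cube$wavenumbers,
                      ph$cube$pixel_pitch)
  expect_equal(ch_oh_ratio(cube2, seg), c1, tolerance = 1e-12)
})

test_that("hydration ratio responds monotonically to the hydration knob", {
  r <- vapply(c(0.9, 0.45), function(h) {
    ph <- make_raman_phantom(cell_phantom_spec(hydration = h, ice_fraction = 0,
                                               noise_level = 0, seed = 23),
                             bands = test_bands())
    ch_oh_ratio(ph$cube, ph$truth$segmentation)
  }, numeric(1))
  expect_gt(r[2], r[1])  # halving hydration raises C-H / O-H
  expect_error(ch_oh_ratio(make_raman_phantom(
    cell_phantom_spec(noise_level = 0, seed = 1),
    bands = test_bands())$cube,
    cell_segmentation(matrix(TRUE, 72, 72), NULL, 0.333),
    new_band_window("a", 2875, 2995), new_band_window("b", 2990, 3245)),
    "disjoint")
})

test_that("frozen diameter follows the equivalent-circle formula", {
  # disk mask of area pi um^2 -> diameter 2 um
  px_area <- pi / 0.25^2  # pixels of pitch 0.25 um
  cell <- matrix(FALSE, 30, 30)
  cell[seq_len(round(px_area))] <- TRUE
  seg <- cell_segmentation(cell, NULL, 0.25)
  fd <- frozen_diameter(seg, fresh_mean_diameter = 2)
  expect_equal(fd$diameter_frozen_um, 2, tolerance = 0.01)
  expect_equal(fd$diameter_fraction, fd$diameter_frozen_um / 2)
  expect_error(frozen_diameter(cell_segmentation(cell & FALSE, NULL, 1), 10),
               "empty cell mask")
})

test_that("amide clustering knob and measured Moran's I rank together", {
  knobs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  mi <- vapply(knobs, function(kb) {
    mean(vapply(1:4, function(s) {
      ph <- make_raman_phantom(
        cell_phantom_spec(protein_clustering = kb, ice_fraction = 0,
                          noise_level = 0.05, seed = 100 + s),
        bands = test_bands(c("amide_i", "ch_stretch")))
      am <- integrate_band(ph$cube, band_window("amide_i"))
      morans_I(am, ph$truth$segmentation$cell_mask)$I
    }, numeric(1)))
  }, numeric(1))
  expect_gte(cor(knobs, mi, method = "spearman"), 0.9)
})
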