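make_cube <- function(vals, wn, pitch = 1) {
  raman_cube(vals, wn, pitch)
}

test_that("band integration matches closed forms", {
  # flat spectrum of height h over a window of width w -> h * w everywhere
  wn <- seq(100, 200, by = 5)
  h <- 3
  cube <- make_cube(array(h, c(length(wn), 4, 4)), wn)
  hm <- integrate_band(cube, new_band_window("x", 120, 180))
  expect_equal(unique(as.vector(hm$values)), h * (180 - 120))

  # Gaussian band over +/- 4 sigma with linear-endpoints baseline:
  # integral within 1% of amplitude * sigma * sqrt(2 pi)
  sigma <- 10; A <- 2; ctr <- 500
  wn2 <- seq(ctr - 4 * sigma, ctr + 4 * sigma, by = 1)
  spec <- A * exp(-(wn2 - ctr)^2 / (2 * sigma^2))
  cube2 <- make_cube(array(rep(spec, 4), c(length(wn2), 2, 2)), wn2)
  hm2 <- integrate_band(cube2, new_band_window("g", min(wn2), max(wn2),
                                               baseline = "linear"))
  expect_equal(hm2$values[1, 1], A * sigma * sqrt(2 * pi), tolerance = 0.01)
})

test_that("band integration is linear in cube intensities", {
  set.seed(1)
  wn <- seq(1, 50)
  a <- array(runif(50 * 3 * 3), c(50, 3, 3))
  b <- array(runif(50 * 3 * 3), c(50, 3, 3))
  win <- new_band_window("x", 10, 40)
  ia <- integrate_band(make_cube(a, wn), win)$values
  ib <- integrate_band(make_cube(b, wn), win)$values
  iab <- integrate_band(make_cube(a + 2 * b, wn), win)$values
  expect_equal(iab, ia + 2 * ib, tolerance = 1e-12)
})

test_that("windows outside the cube axis fail with a clear message", {
  cube <- make_cube(array(1, c(10, 2, 2)), 1:10)
  expect_error(integrate_band(cube, new_band_window("x", 50, 60)),
               "overlaps fewer than 2 samples")
})

test_that("noise-free phantom solute map recovers the partitioning contrast", {
  ph <- make_raman_phantom(
    cell_phantom_spec(partition_ratio_true = 2, ice_fraction = 0,
                      noise_level = 0, seed = 1),
    bands = test_bands())
  sol <- integrate_band(ph$cube, band_window("glycerol"))
  seg <- ph$truth$segmentation
  inner <- seg$cell_mask & !mask_boundary(seg$cell_mask)
  d <- EBImage::distmap(1 - seg$cell_mask)
  outer_far <- d > 3
  expect_equal(mean(sol$values[outer_far]) / mean(sol$values[inner]), 2,
               tolerance = 0.01)
})

test_that("Richardson-Lucy restores blurred disks and conserves mass", {
  set.seed(2)
  n <- 64
  truth <- ifelse(cryoraman:::disk_mask(n, n, 32.5, 32.5, 14), 1, 0)
  kern <- cryoraman:::gaussian_kernel(4 / (2 * sqrt(2 * log(2))))
  blurred <- heat_map(cryoraman:::conv2_circ(truth, kern), "disk",
                      pixel_pitch = 1)
  dec <- deconvolve(blurred, psf_fwhm_um = 4, iterations = 10)
  expect_lt(rmse(dec$values, truth), rmse(blurred$values, truth))
  expect_lt(abs(sum(dec$values) - sum(blurred$values)) / sum(blurred$values),
            0.01)
  expect_true(all(dec$values >= 0))
  expect_true(dec$deconvolved)
})

test_that("Richardson-Lucy trivial limits hold", {
  m <- heat_map(matrix(runif(64), 8, 8), "x", 1)
  expect_identical(deconvolve(m, 4, iterations = 0L)$values, m$values)
  flat <- heat_map(matrix(5, 16, 16), "x", 1)
  expect_equal(deconvolve(flat, 4, 10)$values, flat$values, tolerance = 1e-9)
  expect_message(out <- deconvolve(m, psf_fwhm_um = 0.5, iterations = 10),
                 "below one pixel")
  expect_identical(out$values, m$values)
})

test_that("segmentation separates bimodal maps exactly and is scale invariant", {
  v <- matrix(1, 20, 20)
  v[5:10, 5:10] <- 10
  hm <- heat_map(v, "x", 1)
  mask <- segment_substance(hm, min_object_px = 4L)
  expect_identical(mask, v == 10)
  mask2 <- segment_substance(heat_map(v * 137.5, "x", 1), min_object_px = 4L)
  expect_identical(mask2, mask)

  # min_object_px larger than every object: empty mask, not an error
  empty <- segment_substance(hm, min_object_px = 100L)
  expect_false(any(empty))

  expect_error(segment_substance(heat_map(matrix(2, 5, 5), "x", 1)),
               "constant map")
})

test_that("cell segmentation unions amide I and C-H supports", {
  v <- matrix(0.01, 30, 30)
  ch <- v; ch[8:22, 8:22] <- 1            # whole cell
  am <- v; am[8:22, 8:14] <- 1            # amide signal in half the cell
  seg <- segment_cell(heat_map(am, "amide_i", 1), heat_map(ch, "ch_stretch", 1))
  expect_identical(seg$cell_mask, ch == 1)  # union equals C-H support

  # identical maps: same mask as single-map segmentation
  seg2 <- segment_cell(heat_map(ch, "amide_i", 1), heat_map(ch, "ch_stretch", 1))
  expect_identical(seg2$cell_mask,
                   segment_substance(heat_map(ch, "x", 1)))

  expect_error(segment_cell(heat_map(v * 0 + 1e-12, "a", 1),
                            heat_map(v * 0 + 1e-12, "b", 1)))
})

test_that("noise-free phantom cell mask is recovered almost exactly", {
  ph <- make_raman_phantom(cell_phantom_spec(noise_level = 0, seed = 3),
                           bands = test_bands())
  am <- integrate_band(ph$cube, band_window("amide_i"))
  chm <- integrate_band(ph$cube, band_window("ch_stretch"))
  seg <- segment_cell(am, chm)
  truthm <- ph$truth$segmentation$cell_mask
  jac <- sum(seg$cell_mask & truthm) / sum(seg$cell_mask | truthm)
  expect_gte(jac, 0.95)
})

test_that("single cell is recovered across seeds at default noise", {
  hits <- 0L
  seeds <- 1:20
  for (s in seeds) {
    ph <- make_raman_phantom(cell_phantom_spec(seed = s),
                             bands = test_bands(c("amide_i", "ch_stretch")))
    am <- deconvolve(integrate_band(ph$cube, band_window("amide_i")), 0.361)
    chm <- deconvolve(integrate_band(ph$cube, band_window("ch_stretch")),
                      0.361)
    seg <- segment_cell(am, chm)
    jac <- sum(seg$cell_mask & ph$truth$segmentation$cell_mask) /
      sum(seg$cell_mask | ph$truth$segmentation$cell_mask)
    if (jac >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits / length(seeds), 0.95)
})
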