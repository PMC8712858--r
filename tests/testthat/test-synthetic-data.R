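test_that("phantom generation is deterministic and honours the forward model", {
  spec <- cell_phantom_spec(ice_fraction = 0.25, seed = 11)
  a <- make_raman_phantom(spec, bands = test_bands())
  b <- make_raman_phantom(spec, bands = test_bands())
  expect_identical(a$cube$intensities, b$cube$intensities)
  expect_identical(a$truth$segmentation$ice_mask, b$truth$segmentation$ice_mask)

  # noise-free phantom: centre-pixel spectrum equals the analytic band sum
  # (the PSF leaves the field unchanged far from any edge)
  sp0 <- cell_phantom_spec(ice_fraction = 0, partition_ratio_true = 1,
                           protein_clustering = 0, hydration = 0.7,
                           noise_level = 0, seed = 1)
  ph <- make_raman_phantom(sp0, bands = test_bands())
  ctr <- (dim(ph$cube$intensities)[2] + 1) / 2
  wn <- ph$cube$wavenumbers
  reg <- test_bands()
  amp <- c(amide_i = 1, ch_stretch = 0.8, oh_ice = 1.5 * 0.7, glycerol = 1)
  expected <- rowSums(vapply(seq_len(nrow(reg)), function(b) {
    amp[[reg$name[b]]] * exp(-(wn - reg$center[b])^2 / (2 * reg$sigma[b]^2))
  }, numeric(length(wn))))
  expect_equal(ph$cube$intensities[, ctr, ctr], expected, tolerance = 1e-6)
})

test_that("null-contrast phantom has a uniform solute band and no intracellular ice", {
  sp <- cell_phantom_spec(ice_fraction = 0, partition_ratio_true = 1,
                          noise_level = 0, seed = 2)
  ph <- make_raman_phantom(sp, bands = test_bands())
  sol <- integrate_band(ph$cube, band_window("glycerol"))
  expect_lt(diff(range(sol$values)) / mean(sol$values), 1e-8)
  expect_equal(sum(ph$truth$segmentation$ice_mask), 0)
})

test_that("ground-truth cell area matches the requested diameter", {
  ph <- make_raman_phantom(cell_phantom_spec(cell_diameter = 19.8,
                                             noise_level = 0, seed = 3))
  area_um2 <- sum(ph$truth$segmentation$cell_mask) * 0.333^2
  expect_lt(abs(area_um2 - pi * 9.9^2) / (pi * 9.9^2), 0.02)
  expect_equal(ph$truth$diameter_um, 2 * sqrt(area_um2 / pi))
})

test_that("chunky ice is one connected mass; dispersed ice is many separated crystallites", {
  ch <- make_raman_phantom(cell_phantom_spec(ice_fraction = 0.8,
                                             chunky = TRUE, seed = 4),
                           bands = test_bands())
  lab <- EBImage::bwlabel(ch$truth$segmentation$ice_mask)
  expect_equal(max(lab), 1)
  expect_gte(sum(lab == 1) / sum(ch$truth$segmentation$cell_mask), 0.75)

  di <- make_raman_phantom(cell_phantom_spec(ice_fraction = 0.8,
                                             chunky = FALSE, seed = 4),
                           bands = test_bands())
  lab2 <- EBImage::bwlabel(di$truth$segmentation$ice_mask)
  expect_gt(max(lab2), 5)
  expect_lt(max(tabulate(lab2[lab2 > 0])) /
              sum(di$truth$segmentation$cell_mask), 0.75)
  # both hit the requested total fraction up to mask rounding
  expect_equal(di$truth$ice_fraction, 0.8, tolerance = 1e-3)
  expect_equal(ch$truth$ice_fraction, 0.8, tolerance = 1e-3)
})

test_that("oversized cells and unattainable dispersed fractions are rejected", {
  expect_error(make_raman_phantom(cell_phantom_spec(cell_diameter = 30),
                                  image_size = 64L),
               "does not fit")
  expect_error(make_raman_phantom(cell_phantom_spec(ice_fraction = 0.97,
                                                    chunky = FALSE),
                                  bands = test_bands()),
               "not achievable")
})

test_that("calcium movie has the acquisition geometry and exact trivial limits", {
  spec <- calcium_movie_spec(n_responders = 2, n_nonresponders = 1,
                             frame_rate = 4, duration = 185, seed = 5)
  mv <- make_calcium_movie(spec, image_size = 120L)
  expect_equal(dim(mv$movie$frames)[1], 740)  # 185 s at 4 fps
  expect_equal(nrow(mv$truth), 3)

  quiet <- make_calcium_movie(
    calcium_movie_spec(n_responders = 0, n_nonresponders = 3,
                       noise_sd = 0, seed = 6), image_size = 120L)
  v <- apply(quiet$movie$frames, c(2, 3), function(ts) diff(range(ts)))
  expect_equal(max(v), 0)  # every pixel time series constant

  # determinism
  mv2 <- make_calcium_movie(spec, image_size = 120L)
  expect_identical(mv$movie$frames, mv2$movie$frames)
})

test_that("viability tables reproduce requested rates", {
  tab <- make_viability_table(matrix(1, 1, 3), n_cells = 50, seed = 7)
  expect_equal(tab$viable, rep(50, 3))
  expect_equal(tab$timepoint_min, c(0, 30, 60))

  tab2 <- make_viability_table(matrix(0.5, 1, 1), n_cells = 1e4,
                               timepoints = 0, seed = 8)
  expect_lt(abs(tab2$viable / 1e4 - 0.5), 0.02)
})

test_that("freeze logs follow the controlled-rate schedule", {
  fl <- make_freeze_log(freeze_profile(t_nuc = -4, cooling_rate = -1),
                        sampling_dt = 10)
  # hold ends at (20 - (-4))/10 + 15 min; the -60 C ramp lasts (60-4)/1 = 56
  t_leave_hold <- (20 - (-4)) / 10 + 15
  expect_equal(stats::approx(fl$time_min, fl$temperature_c,
                             xout = t_leave_hold)$y, -4)
  expect_equal(stats::approx(fl$time_min, fl$temperature_c,
                             xout = t_leave_hold + 56)$y, -60)
  expect_gt(stats::approx(fl$time_min, fl$temperature_c,
                          xout = t_leave_hold + 55)$y, -60)
  # monotone non-increasing after the hold
  post <- fl$temperature_c[fl$time_min >= t_leave_hold]
  expect_true(all(diff(post) <= 1e-12))
  expect_equal(min(fl$temperature_c), -100)

  # B = -10 with no hold degenerates to a single-rate ramp
  ramp <- make_freeze_log(freeze_profile(t_nuc = -4, cooling_rate = -10,
                                         hold_min = 0), sampling_dt = 30)
  expect_equal(ramp$temperature_c, 20 - 10 * ramp$time_min)

  # the six-condition study grid is expressible
  grid <- expand.grid(t_nuc = c(-4, -8), B = c(-1, -3, -5))
  logs <- mapply(function(tn, b) {
    make_freeze_log(freeze_profile(tn, b), sampling_dt = 60)
  }, grid$t_nuc, grid$B, SIMPLIFY = FALSE)
  expect_length(logs, 6)
  expect_true(all(vapply(logs, function(l) min(l$temperature_c) == -100,
                         logical(1))))
})

test_that("synthetic micrographs carry their true diameters", {
  mg <- make_cell_micrograph(c(8, 10.6, 12), pixel_pitch = 0.5, seed = 9)
  expect_equal(mg$true_diameters_um, c(8, 10.6, 12))
  expect_true(is.matrix(mg$image))
})
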