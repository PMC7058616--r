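# Image-formation simulator: scenes, residual profile, rendering physics.

test_that("scene generation is deterministic and Poisson-distributed", {
  s1 <- generate_scene(extent = 2000, mean_spacing = 75, seed = 11)
  s2 <- generate_scene(extent = 2000, mean_spacing = 75, seed = 11)
  expect_identical(s1, s2)
  s3 <- generate_scene(extent = 2000, mean_spacing = 75, seed = 12)
  expect_false(identical(s1$cells, s3$cells))
  # cell count over a long extent: within 3 sigma of extent / mean spacing
  big <- generate_scene(extent = 10000, mean_spacing = 100, seed = 5)
  expect_lt(abs(length(big$cells) - 100), 3 * sqrt(100) + 1)
  # spacings are positive and cells ordered along the flow axis
  xs <- vapply(big$cells, function(c) c$center[1], numeric(1))
  expect_true(all(diff(xs) > 0))
  # per-cell speed fluctuations respect the truncation bound
  sf <- vapply(big$cells, function(c) c$speed_fluct, numeric(1))
  expect_true(all(abs(sf) <= 0.015))
  # implied throughput at the design point: v / spacing = 10,000 cells/s
  expect_equal(1 / 100e-6, 1e4)
})

test_that("residual speed profile is an odd ramp with the stated edge values", {
  d <- paper_design()
  fx <- fov_x(d)
  expect_equal(residual_speed_profile(fx / 2, d, TRUE), 0)
  expect_equal(residual_speed_profile(fx, d, TRUE), 0.015)
  expect_equal(residual_speed_profile(0, d, TRUE), -0.015)
  expect_equal(residual_speed_profile(fx, d, FALSE), 0.06)
  expect_equal(residual_speed_profile(c(0, fx), d, FALSE), c(-0.06, 0.06))
  expect_error(residual_speed_profile(fx + 1, d, TRUE), "field of view")
})

test_that("phantom invariants are enforced", {
  expect_error(cell_phantom(c(0, 0), cell_radius = 5,
                            droplets = data.frame(x = 10, y = 0, radius = 1,
                                                  density = 1)),
               "inside the cell")
  expect_error(cell_phantom(c(0, 0), nucleus_type = "lobed", n_lobes = 7),
               "n_lobes")
  ph <- cell_phantom(c(10, 10), nucleus_type = "lobed", n_lobes = 3)
  expect_equal(nrow(ph$lobes), 3)
})

test_that("rendering is deterministic per seed and conserves photons", {
  d <- paper_design()
  ph <- cell_phantom(c(40, 9.75), cell_radius = 5, nucleus_radius = 3,
                     droplets = data.frame(x = c(38, 43), y = c(8, 11),
                                           radius = 0.6, density = 500))
  sc <- generate_scene(extent = 80, mean_spacing = 1e6, seed = 1)
  sc$cells <- list(ph)
  mode <- acquisition_mode("VIFFI")
  f1 <- render_frame(sc, mode, d, seed = 9, n_x = 260, n_y = 60)
  f2 <- render_frame(sc, mode, d, seed = 9, n_x = 260, n_y = 60)
  expect_identical(f1$data, f2$data)
  expect_true(all(f1$data >= 0 & f1$data <= 65535))
  expect_true(is.integer(f1$data))
  # photon conservation: no noise, no motion, uniform full-FOV illumination
  un <- acquisition_mode("NO_VIFFI_LONG", exposure_us = 100)
  fr <- render_frame(sc, un, d, noise = NULL, seed = 9, n_x = 260, n_y = 60,
                     motion = FALSE)
  expected <- (100 * pi * 3^2 + 30 * pi * 5^2 + 2 * 500 * pi * 0.6^2) * 100
  # rasterization quantizes structure areas to whole pixels (~1% at this size)
  expect_equal(sum(fr$data), expected, tolerance = 0.02)
  # droplet flux alone is analytic, conserved to numerical tolerance
  ph2 <- cell_phantom(c(40, 9.75), cell_radius = 5, nucleus_density = 0,
                      cytoplasm_density = 0,
                      droplets = data.frame(x = 40, y = 9.75, radius = 0.8,
                                            density = 500))
  sc$cells <- list(ph2)
  fr2 <- render_frame(sc, un, d, noise = NULL, seed = 9, n_x = 260, n_y = 60,
                      motion = FALSE)
  expect_equal(sum(fr2$data), 500 * pi * 0.8^2 * 100, tolerance = 1e-6)
})

test_that("static and frozen renders agree when drift and fluctuations vanish", {
  d <- paper_design()
  sc <- generate_scene(extent = 80, mean_spacing = 1e6, seed = 2)
  sc$cells <- list(cell_phantom(c(40, 9.75), cell_radius = 4, nucleus_radius = 2.5,
                                speed_fluct = 0))
  un <- acquisition_mode("NO_VIFFI_LONG", exposure_us = 50)
  moving <- render_frame(sc, un, d, noise = NULL, seed = 3, n_x = 260, n_y = 60,
                         residual_args = list(amp_on = 0, amp_off = 0))
  # zero residual + zero fluctuation in a cancellation-free mode still drifts
  # at v; the true identity case is the VIFFI mode with zero residual
  vf <- acquisition_mode("VIFFI", exposure_us = 50)
  frozen <- render_frame(sc, vf, d, noise = NULL, seed = 3, n_x = 260, n_y = 60,
                         residual_args = list(amp_on = 0))
  static <- render_frame(sc, vf, d, noise = NULL, seed = 3, n_x = 260, n_y = 60,
                         motion = FALSE)
  expect_equal(frozen$data, static$data, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(moving$data, static$data)))
})

test_that("a point emitter streaks by v t_exp without cancellation", {
  d <- paper_design()
  sc <- generate_scene(extent = 455, mean_spacing = 1e6, seed = 1)
  sc$cells <- list()
  sc$beads <- data.frame(x = 230, y = 9.75, rate = 50)
  long <- acquisition_mode("NO_VIFFI_LONG")  # 340 us
  fr <- render_frame(sc, long, d, noise = NULL, seed = 3, n_x = 1400, n_y = 60)
  prof <- colSums(split_channels(fr)[[1]])
  streak_um <- sum(prof > max(prof) / 2) * fr$pixel_size
  expect_equal(streak_um, 340, tolerance = 0.01)
})

test_that("short-exposure beads are blur-free within a tenth of a pixel", {
  d <- paper_design()
  short <- acquisition_mode("NO_VIFFI_SHORT")  # 0.3 us -> 0.3 um drift
  bf <- render_bead_field(20, d, short, noise = NULL, seed = 4, n_x = 600,
                          n_y = 60, bead_rate = 2e4)
  ch <- split_channels(bf)[[1]]
  p <- bf$pixel_size
  sig0 <- 0.21 * 530 / 1e3 / 0.75
  for (i in seq_len(nrow(bf$truth))) {
    cr <- crop_at_peak(ch, bf$truth$x[i], bf$truth$y[i], p)
    if (is.null(cr)) next
    f <- fit_psf(cr$crop, p)
    # drift over 0.3 us adds sqrt(sig^2 + (v t)^2 / 12) - sig ~ 0.025 um blur
    expect_lt(f$sigma_x_um - f$sigma_y_um, 0.1 * p)
  }
})

test_that("VIFFI bead blur matches the kinematic residual-drift product", {
  d <- paper_design()
  # bead pinned at the FOV edge: residual fraction 1.5%, local exposure ~10 us
  tr <- data.frame(x = fov_x(d) - 10, y = 9.75, rate = 1000, speed_fluct = 0)
  fr <- viffi:::render_frame_beads(NULL, tr, acquisition_mode("VIFFI"), d,
                                   NULL, 1, n_x = 2554, n_y = 60)
  ch <- split_channels(fr)[[1]]
  cr <- crop_at_peak(ch, tr$x, tr$y, fr$pixel_size)
  f <- fit_psf(cr$crop, fr$pixel_size)
  # expected blur: drift 0.015 v over the ~10-us beam passage ~ 0.15 um,
  # i.e. a box of that length added in quadrature to the PSF
  sig0 <- 0.21 * 530 / 1e3 / 0.75
  blur <- 0.015 * 1 * local_exposure_time(26, 2.54)
  sig_exp <- sqrt(sig0^2 + blur^2 / 12)
  expect_equal(f$sigma_x_um, sig_exp, tolerance = 0.1)
  expect_equal(f$sigma_y_um, sig0, tolerance = 0.05)
})

test_that("frame I/O round-trips pixels and metadata", {
  d <- paper_design()
  bf <- render_bead_field(5, d, acquisition_mode("VIFFI"), seed = 6,
                          n_x = 200, n_y = 40)
  path <- tempfile(fileext = ".tif")
  write_frame(bf, path)
  rd <- read_frame(path)
  expect_identical(rd$data, bf$data)
  expect_equal(rd$pixel_size, bf$pixel_size)
  expect_equal(rd$mode, "VIFFI")
  expect_equal(as.data.frame(rd$truth)[, c("x", "y")],
               bf$truth[, c("x", "y")], tolerance = 1e-12)
  # channel split inverts the stacked layout exactly
  chans <- split_channels(rd)
  expect_identical(rbind(chans[[1]], chans[[2]]), rd$data)
})
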