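# Segmentation, enclosing-box morphometry, droplet counting, PSF fitting,
# feature export.

test_that("segmentation recovers disks and separates distant components", {
  blank <- matrix(100, 60, 60)
  expect_equal(length(segment(blank)$sizes), 0)
  img <- matrix(100, 80, 80)
  img[disk_mask(80, 40, 40, 15)] <- 1000
  seg <- segment(img)
  expect_equal(length(seg$sizes), 1)
  expect_equal(seg$sizes[1], pi * 15^2, tolerance = 0.05)
  # two disks separated well beyond the closing radius
  img2 <- matrix(100, 80, 80)
  img2[disk_mask(80, 22, 40, 10)] <- 1000
  img2[disk_mask(80, 58, 40, 10)] <- 1000
  seg2 <- segment(img2)
  expect_equal(length(seg2$sizes), 2)
  # labels contiguous from 1
  expect_setequal(setdiff(unique(as.vector(seg2$labels)), 0L), c(1L, 2L))
})

test_that("minimum-area rectangle matches the brute-force rotation search", {
  set.seed(42)
  for (i in 1:50) {
    pts <- matrix(runif(2 * sample(5:40, 1), 0, 30), ncol = 2)
    fast <- min_area_rect(pts)$area
    slow <- brute_min_rect_area(pts)
    expect_lt(abs(fast - slow) / max(slow, 1e-9), 1e-3)
    expect_lte(fast, slow + 1e-9)  # calipers is exact, search is an upper bound
  }
})

test_that("enclosing-box ratio hits the analytic identities", {
  # full axis-aligned rectangle: ratio exactly 1
  rect <- matrix(FALSE, 30, 30)
  rect[5:20, 8:25] <- TRUE
  expect_equal(as.numeric(enclosing_box_ratio(rect)), 1, tolerance = 1e-9)
  # large discrete disk tends to pi/4
  dsk <- disk_mask(220, 110, 110, 100)
  expect_equal(as.numeric(enclosing_box_ratio(dsk)), pi / 4, tolerance = 0.02)
  expect_error(enclosing_box_ratio(matrix(FALSE, 5, 5)), "empty")
})

test_that("enclosing-box ratio is rotation-invariant within discretization", {
  base <- lobed_mask(320, 160, 160, 60, 3)
  expect_gt(sum(base), 500)
  r0 <- as.numeric(enclosing_box_ratio(base))
  for (ang in c(20, 45, 77, 130)) {
    r1 <- as.numeric(enclosing_box_ratio(rotate_mask(base, ang)))
    expect_lt(abs(r1 - r0), 0.02)
  }
})

test_that("droplet counting recovers constructed spot fields exactly", {
  blank <- matrix(100, 48, 48)
  expect_equal(count_droplets(blank, 5, 300)$count, 0)
  for (k in c(1, 3, 6)) {
    sp <- make_spot_image(k = k, amp = 600, min_sep = 12, seed = k)
    res <- count_droplets(sp$image, 5, 300)
    expect_equal(res$count, k)
    # positions within one pixel of ground truth (matched by nearest)
    for (i in seq_len(k)) {
      dmin <- min(sqrt((res$positions[, 1] - sp$centers[i, 1])^2 +
                       (res$positions[, 2] - sp$centers[i, 2])^2))
      expect_lt(dmin, 1)
    }
  }
  # below-threshold spots are rejected
  lo <- make_spot_image(k = 3, amp = 200, min_sep = 12, seed = 9)
  expect_equal(count_droplets(lo$image, 5, 300)$count, 0)
})

test_that("droplet counting is offset-invariant and threshold-monotone", {
  sp <- make_spot_image(k = 4, amp = 600, min_sep = 12, seed = 3)
  r1 <- count_droplets(sp$image, 5, 300)
  r2 <- count_droplets(sp$image + 5000, 5, 300)
  expect_equal(r1$count, r2$count)
  expect_equal(r1$positions, r2$positions)
  # doubling amplitude relative to a fixed threshold never loses spots
  sp2 <- sp$image
  sp2 <- (sp2 - 100) * 2 + 100
  expect_gte(count_droplets(sp2, 5, 300)$count, r1$count)
})

test_that("cell features match analytic area, symmetry and scaling", {
  dsk <- disk_mask(60, 30, 30, 20)
  f <- cell_features(dsk, pixel_size = 0.325)
  expect_equal(f$area_um2, pi * (20 * 0.325)^2, tolerance = 0.05)
  sq <- matrix(FALSE, 40, 40)
  sq[10:29, 10:29] <- TRUE
  fs <- cell_features(sq)
  expect_equal(fs$aspect_ratio, 1, tolerance = 1e-6)
  # doubling the radius quadruples area and doubles perimeter (within 5%)
  f2 <- cell_features(disk_mask(100, 50, 50, 40), pixel_size = 0.325)
  expect_equal(f2$area_px / f$area_px, 4, tolerance = 0.05)
  expect_equal(f2$perimeter_um / f$perimeter_um, 2, tolerance = 0.05)
  expect_error(cell_features(matrix(FALSE, 5, 5)), "empty")
})

test_that("PSF fitting recovers noiseless Gaussians to 1e-3", {
  for (sig in c(1.0, 1.8, 2.5)) {
    g <- 500 * exp(-((matrix(rep(1:25, each = 25), 25) - 13.2)^2 +
                     (matrix(rep(1:25, times = 25), 25) - 12.6)^2) / (2 * sig^2)) + 40
    f <- fit_psf(g, pixel_size = 1)
    expect_true(f$converged)
    expect_equal(f$sigma_x_um, sig, tolerance = 1e-3)
    expect_equal(f$sigma_y_um, sig, tolerance = 1e-3)
    expect_equal(f$fwe1m_x_um, 2 * sqrt(2) * f$sigma_x_um, tolerance = 1e-12)
  }
  # closed-form identity: sigma = 1 px gives FWe1M = 2.828 px
  g1 <- 300 * exp(-((matrix(rep(1:15, each = 15), 15) - 8)^2 +
                    (matrix(rep(1:15, times = 15), 15) - 8)^2) / 2)
  expect_equal(fit_psf(g1)$fwe1m_x_um, 2 * sqrt(2), tolerance = 1e-3)
})

test_that("PSF fitting localizes rendered beads to sub-pixel accuracy", {
  d <- paper_design()
  bf <- isolated_bead_field(40, d, acquisition_mode("VIFFI"),
                            noise = sensor_noise(), seed = 21,
                            bead_rate = 100, motion = FALSE)
  ch <- split_channels(bf)[[1]]
  p <- bf$pixel_size
  errs <- c()
  for (i in seq_len(nrow(bf$truth))) {
    cr <- crop_at_peak(ch, bf$truth$x[i], bf$truth$y[i], p)
    if (is.null(cr)) next
    f <- fit_psf(cr$crop, p)
    if (!f$converged) next
    fit_x <- f$center_um[1] + (cr$pc - 9) * p
    fit_y <- f$center_um[2] + (cr$pr - 9) * p
    errs <- c(errs, sqrt((fit_x - bf$truth$x[i])^2 + (fit_y - bf$truth$y[i])^2))
  }
  expect_gt(length(errs), 20)
  expect_lt(median(errs) / p, 0.2)
})

test_that("droplet statistics treat zero-droplet cells as missing", {
  st <- droplet_area_stats(list(c(2), c(1, 3), numeric(0)))
  expect_equal(st$droplet_count, c(1L, 2L, 0L))
  expect_equal(st$mean_droplet_area_um2, c(2, 2, NA_real_))
})

test_that("feature export round-trips and crops are centered on the phantom", {
  rec <- data.frame(frame = 1L, cell_id = 1:2, x_um = c(10, 20),
                    y_um = c(8, 9), area_um2 = c(75, 80),
                    perimeter_um = c(31, 33), aspect_ratio = c(1, 1.2),
                    nucleus_area_um2 = c(28, 30), box_area_um2 = c(40, 44),
                    box_ratio = c(0.7, 0.68), droplet_count = c(2L, 0L),
                    mean_droplet_area_um2 = c(1.1, NA))
  path <- tempfile(fileext = ".csv")
  export_features(rec, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2)
  expect_equal(names(back), names(rec))
  expect_equal(back, rec, tolerance = 1e-12)
  expect_error(export_features(rec[, -3], path), "missing columns")

  # crops: bright pixel at a known position ends up at the crop center
  img <- matrix(0, 60, 60)
  img[30, 40] <- 5000
  p <- 0.325
  rc <- data.frame(cell_id = 1L, x_um = (40 - 0.5) * p, y_um = (30 - 0.5) * p)
  dir <- tempfile()
  paths <- export_crops(img, rc, p, dir, size = 16)
  crop <- round(tiff::readTIFF(paths[1]) * 65535)
  pk <- which(crop == max(crop), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(pk - c(9, 9))), 1)
})

test_that("full pipeline separates lobulated from round nuclei on a rendered frame", {
  d <- paper_design()
  mk_cell <- function(lobed) function(id, center, sf) {
    cell_phantom(center, cell_radius = 5,
                 nucleus_type = if (lobed) "lobed" else "disk",
                 n_lobes = 3, nucleus_radius = 3, nucleus_density = 150,
                 cytoplasm_density = 60, speed_fluct = sf,
                 lobe_angle = stats::runif(1, 0, 2 * pi))
  }
  ratios <- function(lobed, seed) {
    sc <- generate_scene(extent = 240, mean_spacing = 60, seed = seed,
                         y_center = 9.75, y_jitter = 2,
                         cell_generator = mk_cell(lobed))
    fr <- render_frame(sc, acquisition_mode("VIFFI"), d, seed = seed,
                       n_x = 760, n_y = 60, photon_scale = 2)
    rec <- analyze_frame(fr, droplet_threshold = NULL)
    rec$box_ratio[!is.na(rec$box_ratio)]
  }
  r_round <- unlist(lapply(1:3, function(s) ratios(FALSE, s)))
  r_lobed <- unlist(lapply(4:6, function(s) ratios(TRUE, s)))
  expect_gt(length(r_round), 3)
  expect_gt(length(r_lobed), 3)
  expect_gt(median(r_round), median(r_lobed))
})
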