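# Optical-design constraint solver: scan range, magnification window, facet
# fit, timing budget, flow geometry.

test_that("scan range matches term-by-term evaluation and symmetry cases", {
  d <- paper_design()
  # independent term-by-term oracle of the scan-range relation
  a <- 45 * pi / 180
  r <- 13.5 * 0.2 / 70
  cn <- cos(pi / 28)
  oracle_mm <- 4 * 9 * 0.2 *
    (2 * pi / 28 + asin((-r + sin(a)) * cn) - asin((r + sin(a)) * cn))
  expect_equal(max_scan_range(d), oracle_mm * 1e3, tolerance = 1e-12)
  expect_equal(signif_half_up(max_scan_range(d), 2), 840)  # ~8.4e2 um
  expect_gt(max_scan_range(d), 0)
  # d_obj -> 0: asin terms cancel, leaving 4 f_o M (2 pi / N) exactly
  d0 <- viffi_design(d_obj = 1e-12)
  expect_equal(d0$d_obj, 1e-12)
  expect_equal(max_scan_range(d0), 4 * 9 * 0.2 * 2 * pi / 28 * 1e3,
               tolerance = 1e-6)
  # geometric infeasibility raises a domain error
  expect_error(max_scan_range(viffi_design(alpha = 89.9, d_obj = 60, d_poly = 61)),
               "infeasible")
})

test_that("scan range is monotone in focal length and back-aperture diameter", {
  f_grid <- seq(5, 15, by = 1)
  scans <- vapply(f_grid, function(f) max_scan_range(viffi_design(f_o = f)),
                  numeric(1))
  expect_true(all(diff(scans) > 0))
  d_grid <- seq(5, 20, by = 1)
  scans_d <- vapply(d_grid, function(dd) max_scan_range(viffi_design(d_obj = dd)),
                    numeric(1))
  expect_true(all(diff(scans_d) < 0))
})

test_that("exposure cap is scan range over twice the flow speed", {
  d <- paper_design()
  expect_equal(max_exposure_from_scan(d), max_scan_range(d) / 2, tolerance = 1e-12)
  expect_equal(round_to(max_exposure_from_scan(d), 10), 420)
  # doubling v halves the cap exactly; cap x v is invariant
  d2 <- viffi_design(v_flow = 2)
  expect_equal(max_exposure_from_scan(d2), max_exposure_from_scan(d) / 2)
  for (v in c(0.25, 0.5, 1, 2, 4)) {
    dv <- viffi_design(v_flow = v)
    expect_equal(max_exposure_from_scan(dv) * v, max_scan_range(d) / 2,
                 tolerance = 1e-9)
  }
})

test_that("magnification window matches direct arithmetic and brackets the chosen M", {
  d <- paper_design()
  mb <- magnification_bounds(d)
  expect_equal(mb$M_low, 1 * 0.8e-3 * 28 / (4 * pi * 9e-3), tolerance = 1e-12)
  expect_equal(mb$M_high, 16.6e-3 * 28 / (4 * pi * 0.18), tolerance = 1e-12)
  expect_true(mb$contains_M_relay)
  expect_lt(mb$M_low, 0.2)
  expect_gt(mb$M_high, 0.2)
  # v -> 0 drives the lower bound to 0
  expect_lt(magnification_bounds(viffi_design(v_flow = 1e-9))$M_low, 1e-9)
  # no feasible window errors
  expect_error(magnification_bounds(viffi_design(v_flow = 50)), "feasible")
})

test_that("facet fit compares beam footprint against polygon facet width", {
  d <- paper_design()
  ff <- facet_fit_check(d)
  expect_equal(ff$footprint_mm, 2.7)
  expect_equal(ff$facet_width_mm, 70 * tan(pi / 28), tolerance = 1e-12)
  expect_true(ff$pass)
  # boundary: footprint equal to facet width fails (strict inequality)
  m_eq <- ff$facet_width_mm / d$d_obj
  expect_false(facet_fit_check(viffi_design(M_relay = m_eq))$pass)
  expect_false(facet_fit_check(viffi_design(M_relay = 2 * m_eq))$pass)
})

test_that("timing budget reproduces readout time and flags violations by name", {
  d <- paper_design()
  tb <- timing_budget(d, 340)
  expect_equal(tb$t_readout, 16.6e-3 * 88 / (572e6 * 6.5e-6) * 1e6,
               tolerance = 1e-9)  # ~393 us
  expect_true(tb$pass)
  tb2 <- timing_budget(d, 500)
  expect_false(tb2$checks$exposure_within_scan_cap$pass)
  expect_false(tb2$pass)
  # the reported value is never clamped
  expect_equal(tb2$t_exposure, 500)
  # frame-period consistency: (FOV_x - l_overlap) / v = T_s at the operating point
  expect_equal((fov_x(d) - d$l_overlap) / d$v_flow, 800, tolerance = 1e-6)
})

test_that("design report and JSON round trip are consistent", {
  d <- paper_design()
  rep <- design_report(d)
  expect_true(rep$pass)
  expect_true(all(vapply(rep[names(rep) != "pass"], function(x) isTRUE(x$pass),
                         logical(1))))
  path <- tempfile(fileext = ".json")
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(unclass(d2), unclass(d))
})

test_that("design constructor rejects invalid parameterizations", {
  expect_error(viffi_design(f_o = -1), "positive")
  expect_error(viffi_design(alpha = 95), "alpha")
  expect_error(viffi_design(N_facets = 2), "N_facets")
  expect_error(viffi_design(v_flow = 0), "positive")
})

test_that("sample-core diameter follows the equal-area rule", {
  g <- flow_cell_geometry()
  expect_equal(round_half_up(sample_flow_diameter(g)), 13)
  g2 <- flow_cell_geometry(flow_ratio = 1 / 3900)
  expect_equal(sample_flow_diameter(g2), 2 * sqrt(400 * 250 / 3901 / pi),
               tolerance = 1e-12)
  expect_equal(signif_half_up(sample_flow_diameter(g2), 2), 5.7)
  # ratio -> 0 gives diameter -> 0
  expect_lt(sample_flow_diameter(flow_cell_geometry(flow_ratio = 1e-12)), 1e-3)
})

test_that("laminar speed variation over the core is small and grid-converged", {
  g <- flow_cell_geometry()
  v13 <- laminar_speed_variation(g, 13)
  expect_lt(v13, 0.01)
  expect_gt(v13, 0)
  expect_equal(laminar_speed_variation(g, 0), 0)
  # refinement oracle: square duct, core 10% of width, dense grid
  sq <- flow_cell_geometry(200, 200)
  coarse <- laminar_speed_variation(sq, 20)
  dense <- laminar_speed_variation(sq, 20, n_r = 80, n_theta = 360)
  expect_lt(abs(coarse - dense), 1e-3)
  # variation grows with core size
  expect_gt(laminar_speed_variation(g, 40), v13)
  expect_error(laminar_speed_variation(g, 300), "smaller")
})
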