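#' Instrument design parameterization
#'
#' Bundles the optical, scanner, camera and flow parameters of a
#' virtual-freezing imaging flow cytometer. Defaults are the published
#' operating point of the demonstrated instrument: a 20x NA 0.75 objective
#' (f = 9 mm) with a 180-mm tube lens, a 0.2x relay onto a 28-facet polygon
#' scanner of 70-mm inner diameter, and an sCMOS camera read out over an
#' 88-line region of interest at a 0.8-ms frame period while cells flow at
#' 1 m/s.
#'
#' Note on symbols: the field's design equations reuse one symbol for both the
#' polygon inner diameter and the camera pixel size; here they are named
#' distinctly (`d_poly` vs `d_pix`).
#'
#' @param f_o objective focal length \[mm\].
#' @param f_t tube-lens focal length \[mm\].
#' @param M_relay magnification of the first relay system (dimensionless).
#' @param M_total total imaging magnification (dimensionless).
#' @param N_facets number of polygon facets (integer, >= 3).
#' @param d_poly polygon inner diameter \[mm\].
#' @param d_obj objective back-aperture diameter \[mm\].
#' @param alpha nominal incidence angle on the polygon \[degrees\].
#' @param L_x sensor length in the flow direction \[mm\].
#' @param d_pix camera pixel size \[µm\].
#' @param N_y number of sensor lines perpendicular to the flow (integer).
#' @param f_p camera pixel data rate \[Hz\].
#' @param T_s frame period \[s\].
#' @param v_flow cell flow speed \[m/s\].
#' @param l_overlap frame-to-frame overlap length in the object plane \[µm\].
#' @return an object of class `viffi_design` (a validated named list).
#' @examples
#' d <- viffi_design()
#' pixel_size(d)   # 0.325 um in the object plane
#' frame_rate(d)   # 1250 fps
#' @export
viffi_design <- function(f_o = 9, f_t = 180, M_relay = 0.2, M_total = 20,
                         N_facets = 28L, d_poly = 70, d_obj = 13.5,
                         alpha = 45, L_x = 16.6, d_pix = 6.5, N_y = 88L,
                         f_p = 572e6, T_s = 0.8e-3, v_flow = 1.0,
                         l_overlap = 30) {
  check_positive(f_o = f_o, f_t = f_t, M_relay = M_relay, M_total = M_total,
                 d_poly = d_poly, d_obj = d_obj, L_x = L_x, d_pix = d_pix,
                 f_p = f_p, T_s = T_s, v_flow = v_flow)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 90) {
    stop("'alpha' must lie strictly between 0 and 90 degrees", call. = FALSE)
  }
  if (N_facets < 3 || N_facets != round(N_facets)) {
    stop("'N_facets' must be an integer >= 3", call. = FALSE)
  }
  if (N_y < 1 || N_y != round(N_y)) stop("'N_y' must be a positive integer", call. = FALSE)
  if (!is.finite(l_overlap) || l_overlap < 0) stop("'l_overlap' must be >= 0", call. = FALSE)
  d <- list(f_o = f_o, f_t = f_t, M_relay = M_relay, M_total = M_total,
            N_facets = as.integer(N_facets), d_poly = d_poly, d_obj = d_obj,
            alpha = alpha, L_x = L_x, d_pix = d_pix, N_y = as.integer(N_y),
            f_p = f_p, T_s = T_s, v_flow = v_flow, l_overlap = l_overlap)
  class(d) <- "viffi_design"
  d
}

#' @export
print.viffi_design <- function(x, ...) {
  cat("<viffi_design>\n")
  cat(sprintf("  objective f = %g mm, tube lens f = %g mm, M_relay = %g, M_total = %gx\n",
              x$f_o, x$f_t, x$M_relay, x$M_total))
  cat(sprintf("  polygon: %d facets, inner diameter %g mm, incidence %g deg\n",
              x$N_facets, x$d_poly, x$alpha))
  cat(sprintf("  camera: L_x = %g mm, %g um pixels, %d lines, %.0f MHz pixel rate, T_s = %g ms\n",
              x$L_x, x$d_pix, x$N_y, x$f_p / 1e6, x$T_s * 1e3))
  cat(sprintf("  flow: %g m/s; object-plane pixel %g um; FOV %g x %g um\n",
              x$v_flow, pixel_size(x), fov_x(x), fov_y(x)))
  invisible(x)
}

#' Object-plane pixel size \[µm\]
#' @param design a [viffi_design()].
#' @return pixel size in the object plane (`d_pix / M_total`) \[µm\].
#' @export
pixel_size <- function(design) design$d_pix / design$M_total

#' Field of view in the flow direction \[µm\]
#' @param design a [viffi_design()].
#' @return `L_x / M_total`, in µm.
#' @export
fov_x <- function(design) design$L_x * 1e3 / design$M_total

#' Field of view perpendicular to the flow \[µm\]
#' @param design a [viffi_design()].
#' @return `N_y d_pix / M_total`, in µm.
#' @export
fov_y <- function(design) design$N_y * design$d_pix / design$M_total

#' Frame rate \[frames/s\]
#' @param design a [viffi_design()].
#' @return `1 / T_s`.
#' @export
frame_rate <- function(design) 1 / design$T_s

#' Maximum polygon-scanner scan range in the object plane
#'
#' Evaluates the scan-range design relation for a polygon scanner whose facets
#' sit in the Fourier plane of the fluorescence: the angular interval a single
#' facet can sweep while the beam footprint stays on that facet, mapped into
#' object-plane length through the objective and relay magnification,
#'
#' \deqn{L = 4 f_o M \left\{ \frac{2\pi}{N} +
#'   \arcsin\!\big[(-d_o M / d_p + \sin\alpha)\cos(\pi/N)\big] -
#'   \arcsin\!\big[( d_o M / d_p + \sin\alpha)\cos(\pi/N)\big] \right\}}
#'
#' A feasible design requires L > 0.
#'
#' @param design a [viffi_design()].
#' @return scan range \[µm\].
#' @examples
#' max_scan_range(viffi_design())  # about 838 um
#' @export
max_scan_range <- function(design) {
  stopifnot(inherits(design, "viffi_design"))
  a <- deg2rad(design$alpha)
  r <- design$d_obj * design$M_relay / design$d_poly
  c_n <- cos(pi / design$N_facets)
  arg_lo <- (-r + sin(a)) * c_n
  arg_hi <- (r + sin(a)) * c_n
  if (abs(arg_lo) > 1 || abs(arg_hi) > 1) {
    stop("design geometrically infeasible: arcsine argument outside [-1, 1]",
         call. = FALSE)
  }
  l_mm <- 4 * design$f_o * design$M_relay *
    (2 * pi / design$N_facets + asin(arg_lo) - asin(arg_hi))
  l_mm * 1e3
}

#' Exposure-time upper limit imposed by the scan range
#'
#' The polygon can only cancel motion while the sweep stays within the
#' feasible scan range; since the camera's field of view co-moves with the
#' flow during the exposure, the usable range is traversed at twice the flow
#' speed and the exposure cap is `max_scan_range / (2 v_flow)`. At the default
#' design this reproduces the 420-µs limit (to the nearest 10 µs).
#'
#' @param design a [viffi_design()].
#' @return exposure upper limit \[µs\].
#' @examples
#' max_exposure_from_scan(viffi_design())  # about 419 us
#' @export
max_exposure_from_scan <- function(design) {
  if (design$v_flow <= 0) stop("'v_flow' must be > 0", call. = FALSE)
  max_scan_range(design) / (2 * design$v_flow)  # um / (m/s) == um/(um/us) = us
}

#' Feasible magnification window for the first relay system
#'
#' Lower bound: the image must traverse less than one facet sweep during one
#' frame period (`v T_s N / (4 pi f_o)`). Upper bound: the swept image must
#' stay on the sensor (`L_x N / (4 pi f_t)`).
#'
#' @param design a [viffi_design()].
#' @return list with `M_low`, `M_high`, and `contains_M_relay` (logical).
#' @examples
#' magnification_bounds(viffi_design())  # about (0.198, 0.205), contains 0.2
#' @export
magnification_bounds <- function(design) {
  stopifnot(inherits(design, "viffi_design"))
  m_low <- design$v_flow * design$T_s * design$N_facets / (4 * pi * design$f_o * 1e-3)
  m_high <- design$L_x * design$N_facets / (4 * pi * design$f_t)
  if (m_low >= m_high) {
    stop(sprintf("no feasible magnification: lower bound %.4g >= upper bound %.4g",
                 m_low, m_high), call. = FALSE)
  }
  list(M_low = m_low, M_high = m_high,
       contains_M_relay = design$M_relay > m_low && design$M_relay < m_high)
}

#' Check that the fluorescence beam fits on one polygon facet
#'
#' The relayed back-aperture image (diameter `d_obj * M_relay`) must be
#' strictly smaller than the facet width, taken as `d_poly * tan(pi/N)` for a
#' polygon of inner (inscribed-circle) diameter `d_poly`.
#'
#' @param design a [viffi_design()].
#' @return list with `pass` (logical), `footprint_mm`, `facet_width_mm`,
#'   `margin_mm` (facet width minus footprint).
#' @export
facet_fit_check <- function(design) {
  stopifnot(inherits(design, "viffi_design"))
  footprint <- design$d_obj * design$M_relay
  facet <- design$d_poly * tan(pi / design$N_facets)
  list(pass = footprint < facet, footprint_mm = footprint,
       facet_width_mm = facet, margin_mm = facet - footprint)
}

#' Acquisition timing budget
#'
#' Checks a candidate exposure time against the two hard timing constraints:
#' the scan-range exposure cap, and the requirement that sensor readout plus
#' exposure fit inside the frame period. Readout time is
#' `L_x N_y / (f_p d_pix)` (line-wise rolling readout at the pixel data rate).
#' Violations are reported as named failed constraints, never clamped.
#'
#' @param design a [viffi_design()].
#' @param t_exposure camera exposure time \[µs\].
#' @return object of class `viffi_timing`: a list with `t_exposure`,
#'   `t_readout`, `t_exp_max_scan`, `scan_range_max` (µm), `frame_period_us`,
#'   a `checks` list of `(value, bound, pass)` per constraint, and overall
#'   `pass`.
#' @examples
#' timing_budget(viffi_design(), t_exposure = 340)
#' @export
timing_budget <- function(design, t_exposure) {
  stopifnot(inherits(design, "viffi_design"))
  check_positive(t_exposure = t_exposure)
  t_read <- design$L_x * 1e-3 * design$N_y / (design$f_p * design$d_pix * 1e-6) * 1e6
  scan_max <- max_scan_range(design)
  t_scan_cap <- max_exposure_from_scan(design)
  frame_us <- design$T_s * 1e6
  checks <- list(
    exposure_within_scan_cap = list(value = t_exposure, bound = t_scan_cap,
                                    pass = t_exposure <= t_scan_cap),
    readout_plus_exposure_within_frame = list(value = t_read + t_exposure,
                                              bound = frame_us,
                                              pass = t_read + t_exposure <= frame_us)
  )
  out <- list(t_exposure = t_exposure, t_readout = t_read,
              t_exp_max_scan = t_scan_cap, scan_range_max = scan_max,
              frame_period_us = frame_us, checks = checks,
              pass = all(vapply(checks, `[[`, logical(1), "pass")))
  class(out) <- "viffi_timing"
  out
}

#' @export
print.viffi_timing <- function(x, ...) {
  cat("<viffi_timing>\n")
  cat(sprintf("  exposure %.1f us | readout %.1f us | scan cap %.1f us | frame %.0f us\n",
              x$t_exposure, x$t_readout, x$t_exp_max_scan, x$frame_period_us))
  for (nm in names(x$checks)) {
    ck <- x$checks[[nm]]
    cat(sprintf("  %-36s %8.1f <= %8.1f  [%s]\n", nm, ck$value, ck$bound,
                if (ck$pass) "ok" else "FAIL"))
  }
  invisible(x)
}

#' Full design-constraint report
#'
#' Evaluates every design constraint (scan-range positivity, magnification
#' window, facet fit, timing budget) and returns a machine-readable report of
#' `(value, bound, pass)` entries, as emitted by the `design validate` command.
#'
#' @param design a [viffi_design()].
#' @param t_exposure exposure used for the timing checks \[µs\]; default 340.
#' @return named list of constraint entries plus overall `pass`.
#' @export
design_report <- function(design, t_exposure = 340) {
  scan <- tryCatch(max_scan_range(design), error = function(e) NA_real_)
  mb <- tryCatch(magnification_bounds(design), error = function(e) NULL)
  ff <- facet_fit_check(design)
  rep <- list(
    scan_range_positive = list(value = scan, bound = 0,
                               pass = is.finite(scan) && scan > 0),
    magnification_in_window = list(
      value = design$M_relay,
      bound = if (is.null(mb)) c(NA_real_, NA_real_) else c(mb$M_low, mb$M_high),
      pass = !is.null(mb) && mb$contains_M_relay),
    facet_fit = list(value = ff$footprint_mm, bound = ff$facet_width_mm,
                     pass = ff$pass)
  )
  if (is.finite(scan)) {
    tb <- timing_budget(design, t_exposure)
    rep$exposure_within_scan_cap <- tb$checks$exposure_within_scan_cap
    rep$readout_plus_exposure_within_frame <- tb$checks$readout_plus_exposure_within_frame
  }
  rep$pass <- all(vapply(rep, function(x) isTRUE(x$pass), logical(1)))
  rep
}

#' Read / write an instrument design as JSON
#'
#' Serialization uses the field names of [viffi_design()] verbatim.
#'
#' @param design a [viffi_design()].
#' @param path file path.
#' @return `write_design` returns `path` invisibly; `read_design` a
#'   `viffi_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "viffi_design"))
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(viffi_design, vals[names(vals) %in% names(formals(viffi_design))])
}
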