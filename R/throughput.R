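#' Effective line rate
#'
#' Data-acquisition-speed metric of an imaging flow cytometer that is
#' independent of cell spacing: the flow speed divided by the object-plane
#' pixel size in the flow direction. 1 m/s over 0.325-µm pixels gives
#' ~3.1 MHz; a TDI system at 0.039 m/s gives 0.12 MHz.
#'
#' @param v flow speed \[m/s\].
#' @param p_x object-plane pixel size in the flow direction \[µm\].
#' @return line rate \[Hz\].
#' @export
effective_line_rate <- function(v, p_x) {
  check_positive(v = v, p_x = p_x)
  v / (p_x * 1e-6)
}

#' Cell throughput from line rate and cell spacing
#'
#' `f_th = p_x f_x / l_cell`: throughput is proportional to the line rate,
#' with the pixel size and the (sample-preparation-determined) average cell
#' spacing as conversion factors.
#'
#' @param p_x object-plane pixel size \[µm\].
#' @param f_x line rate \[Hz\].
#' @param l_cell average cell spacing \[µm\].
#' @return throughput \[cells/s\].
#' @examples
#' cell_throughput(0.325, effective_line_rate(1, 0.325), 100)  # 10,000 cells/s
#' @export
cell_throughput <- function(p_x, f_x, l_cell) {
  check_positive(p_x = p_x, l_cell = l_cell)
  if (any(f_x < 0)) stop("'f_x' must be >= 0", call. = FALSE)
  p_x * f_x / l_cell
}

#' Frame-period self-consistency residual
#'
#' The frame equation balances the time to advance one (overlap-corrected)
#' field of view against readout plus exposure:
#' `(L_x/M - l_0)/v = L_x N_y / (f_p d_pix) + t_exp1`.
#' Returns LHS - RHS in µs; a small residual indicates a self-consistent
#' operating point.
#'
#' @param design a [viffi_design()].
#' @param t_exp1 exposure cap from data transfer \[µs\].
#' @return residual \[µs\].
#' @export
frame_equation_check <- function(design, t_exp1) {
  stopifnot(inherits(design, "viffi_design"))
  lhs <- (fov_x(design) - design$l_overlap) / design$v_flow  # um / (um/us) = us
  t_read <- design$L_x * 1e-3 * design$N_y / (design$f_p * design$d_pix * 1e-6) * 1e6
  lhs - (t_read + t_exp1)
}

#' Operating exposure time and implied SNR
#'
#' The usable exposure is the smaller of the data-transfer cap and the
#' scan-range cap; in the shot-noise-limited regime the SNR scales as
#' `beta * sqrt(t_exp)`.
#'
#' @param t_exp1 exposure cap from data transfer \[µs\].
#' @param t_exp2 exposure cap from scan range \[µs\].
#' @param beta SNR proportionality coefficient \[SNR per sqrt(µs)\].
#' @return list with `t_exp` \[µs\] and `snr`.
#' @export
exposure_time <- function(t_exp1, t_exp2, beta = 1) {
  check_positive(t_exp1 = t_exp1, t_exp2 = t_exp2)
  t_exp <- pmin(t_exp1, t_exp2)
  list(t_exp = t_exp, snr = beta * sqrt(t_exp))
}

#' Trade-off between cross-flow field of view and flow speed
#'
#' For each flow speed, solves the frame equation for the largest integer
#' number of sensor lines `N_y` that still leaves at least `min_exposure` of
#' camera exposure, i.e. `N_y <= ((L_x/M - l_0)/v - min_exposure) f_p d_pix / L_x`,
#' capped by the physical sensor height. `FOV_y = N_y d_pix / M_total`.
#'
#' @param design a [viffi_design()].
#' @param v_grid flow speeds to evaluate \[m/s\].
#' @param min_exposure minimum acceptable exposure \[µs\].
#' @param n_y_sensor physical number of sensor lines available (default 2160,
#'   a full sCMOS frame).
#' @return data.frame with columns `v_m_per_s`, `N_y_max`, `FOV_y_um`,
#'   `t_exp1_us`, `feasible`. Infeasible speeds (no `N_y >= 1`) are reported
#'   as rows with `feasible = FALSE`, not errors. `FOV_y` is non-increasing
#'   in `v`.
#' @export
fov_y_vs_speed <- function(design, v_grid, min_exposure = 340,
                           n_y_sensor = 2160L) {
  stopifnot(inherits(design, "viffi_design"))
  check_positive(min_exposure = min_exposure)
  if (any(v_grid <= 0)) stop("'v_grid' must be strictly positive", call. = FALSE)
  t_line <- design$L_x * 1e-3 / (design$f_p * design$d_pix * 1e-6) * 1e6  # us/line
  rows <- lapply(v_grid, function(v) {
    budget <- (fov_x(design) - design$l_overlap) / v - min_exposure  # us
    n_y <- min(floor(budget / t_line), n_y_sensor)
    if (n_y < 1) {
      data.frame(v_m_per_s = v, N_y_max = NA_integer_, FOV_y_um = NA_real_,
                 t_exp1_us = NA_real_, feasible = FALSE)
    } else {
      t_exp1 <- (fov_x(design) - design$l_overlap) / v - n_y * t_line
      data.frame(v_m_per_s = v, N_y_max = as.integer(n_y),
                 FOV_y_um = n_y * design$d_pix / design$M_total,
                 t_exp1_us = t_exp1, feasible = TRUE)
    }
  })
  do.call(rbind, rows)
}

#' Continuous-recording capacity
#'
#' Number of cells recordable without interruption given on-board storage:
#' frames are `2 N_x N_y` bytes (16-bit, two channels sharing one frame), the
#' storage holds `storage_bytes / frame_bytes` frames, acquired at the frame
#' rate, while cells arrive at `throughput`. At the default design with 1 TB
#' of storage and 10,000 cells/s this is ~18 million cells.
#'
#' @param design a [viffi_design()].
#' @param storage_bytes storage size \[bytes\] (default 1e12, i.e. 1 TB).
#' @param throughput cell arrival rate \[cells/s\] (default 1e4).
#' @param n_x number of pixels per line; default `round(L_x / d_pix)` rounded
#'   up to a multiple of 64 (sensor ROI granularity), 2560 for the default
#'   design.
#' @return list with `frame_bytes`, `n_frames`, `duration_s`, `n_cells`.
#' @export
recording_capacity <- function(design, storage_bytes = 1e12, throughput = 1e4,
                               n_x = NULL) {
  stopifnot(inherits(design, "viffi_design"))
  if (is.null(n_x)) n_x <- 64 * ceiling(design$L_x * 1e3 / design$d_pix / 64)
  frame_bytes <- 2 * n_x * design$N_y
  n_frames <- floor(storage_bytes / frame_bytes)
  duration <- n_frames * design$T_s
  list(frame_bytes = frame_bytes, n_frames = n_frames, duration_s = duration,
       n_cells = duration * throughput)
}
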