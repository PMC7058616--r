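#' Photon budget of the per-pixel signal model
#'
#' Parameters of the per-pixel signal level (in photoelectrons)
#' `S = P C^-1 T n s eta_yield eta_img eta_sensor`: excitation power spread
#' over the beam cross section, illumination time per molecule, number of
#' fluorophores per pixel area, absorption cross section, quantum yield,
#' collection efficiency and sensor quantum efficiency.
#'
#' @param P excitation power \[W\].
#' @param C excitation-beam cross section \[µm²\].
#' @param T_illum illumination time per molecule \[s\].
#' @param n fluorescent molecules per pixel area (count).
#' @param s absorption cross section \[µm²\].
#' @param eta_yield fluorophore quantum yield (0..1).
#' @param eta_img photon collection efficiency of the imaging system (0..1).
#' @param eta_sensor sensor quantum efficiency (0..1).
#' @param sigma_read sensor readout noise \[electrons RMS\].
#' @return object of class `viffi_photon_budget`.
#' @export
photon_budget <- function(P = 1, C = 1, T_illum = 1, n = 1, s = 1,
                          eta_yield = 1, eta_img = 1, eta_sensor = 1,
                          sigma_read = 0) {
  vals <- list(P = P, C = C, T_illum = T_illum, n = n, s = s,
               eta_yield = eta_yield, eta_img = eta_img,
               eta_sensor = eta_sensor, sigma_read = sigma_read)
  if (any(!vapply(vals, function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0), logical(1)))) {
    stop("all photon-budget parameters must be finite and >= 0", call. = FALSE)
  }
  for (nm in c("eta_yield", "eta_img", "eta_sensor")) {
    if (any(vals[[nm]] > 1)) stop(sprintf("'%s' must lie in [0, 1]", nm), call. = FALSE)
  }
  if (C <= 0) stop("'C' must be > 0", call. = FALSE)
  structure(vals, class = "viffi_photon_budget")
}

#' Signal level in photoelectrons
#'
#' Product form of the per-pixel signal model:
#' `S = P C^-1 T n s eta_yield eta_img eta_sensor`.
#'
#' @param budget a [photon_budget()].
#' @return expected signal \[electrons\].
#' @export
signal_electrons <- function(budget) {
  stopifnot(inherits(budget, "viffi_photon_budget"))
  with(unclass(budget),
       P / C * T_illum * n * s * eta_yield * eta_img * eta_sensor)
}

#' Per-pixel SNR under shot plus readout noise
#'
#' `S / sqrt(S + sigma^2)`; reduces to the shot-noise limit `sqrt(S)` when
#' `sigma = 0`.
#'
#' @param S signal \[electrons\], >= 0.
#' @param sigma_read readout noise \[electrons RMS\].
#' @return SNR (dimensionless); 0 where `S = 0`.
#' @export
snr <- function(S, sigma_read = 0) {
  if (any(S < 0)) stop("'S' must be >= 0", call. = FALSE)
  out <- rep(0, length(S))
  nz <- S > 0 | sigma_read > 0
  out[nz] <- S[nz] / sqrt(S[nz] + sigma_read^2)
  out
}

#' Exposure-time extension factor from motion tolerance
#'
#' With motion cancellation, the per-pixel exposure can be extended until the
#' residual image motion (field-dependent cancellation error plus cell-to-cell
#' flow-speed fluctuation) accumulates to one pixel; the extension factor is
#' the reciprocal of the summed fractional speed errors. With a scanned
#' excitation beam the residual error is ±1.5%, giving
#' `1/(0.015+0.015) ≈ 33`; without it at least ±6%, giving `1/(0.06+0.015) ≈ 13`.
#'
#' @param residual_fraction residual motion-speed fraction (e.g. 0.015).
#' @param flow_fluct_fraction cell-to-cell speed-fluctuation fraction.
#' @return extension factor (dimensionless).
#' @export
exposure_extension_factor <- function(residual_fraction, flow_fluct_fraction) {
  check_positive(residual_fraction = residual_fraction,
                 flow_fluct_fraction = flow_fluct_fraction)
  1 / (residual_fraction + flow_fluct_fraction)
}

#' Excitation-efficiency gain from beam confinement
#'
#' Concentrating a fixed excitation power into a light sheet of width
#' `beam_width` instead of spreading it over the whole field of view improves
#' the local excitation efficiency by the reciprocal of the confinement
#' fraction. The fraction is rounded to one significant figure before
#' inversion, matching how the design number is quoted (26/830 -> 0.03 -> 33).
#'
#' @param beam_width excitation-beam width in the flow direction \[µm\].
#' @param FOV_x field of view in the flow direction \[µm\].
#' @return efficiency gain factor (dimensionless).
#' @export
excitation_efficiency_factor <- function(beam_width, FOV_x) {
  check_positive(beam_width = beam_width, FOV_x = FOV_x)
  if (beam_width > FOV_x) stop("'beam_width' must be <= 'FOV_x'", call. = FALSE)
  1 / signif_half_up(beam_width / FOV_x, 1)
}

#' Overall imaging-sensitivity improvement factor
#'
#' With the beam scan on, the exposure-extension factor multiplies the
#' excitation-confinement gain (~33 x 33 ≈ 1000); with it off, only the
#' (smaller) extension factor remains (~13) since a static full-field
#' illumination has no confinement benefit.
#'
#' @param design a [viffi_design()] (provides the field of view).
#' @param scan_on logical; is the excitation beam scanned?
#' @param beam_width beam e^-2 width in the flow direction \[µm\].
#' @param residual_on,residual_off residual-motion speed fractions with and
#'   without the beam scan.
#' @param flow_fluct cell-to-cell flow-speed fluctuation fraction.
#' @return improvement factor (dimensionless).
#' @examples
#' overall_improvement(viffi_design(), scan_on = TRUE)   # ~1000
#' overall_improvement(viffi_design(), scan_on = FALSE)  # ~13
#' @export
overall_improvement <- function(design, scan_on, beam_width = 26,
                                residual_on = 0.015, residual_off = 0.06,
                                flow_fluct = 0.015) {
  stopifnot(inherits(design, "viffi_design"), is.logical(scan_on))
  if (scan_on) {
    exposure_extension_factor(residual_on, flow_fluct) *
      excitation_efficiency_factor(beam_width, fov_x(design))
  } else {
    exposure_extension_factor(residual_off, flow_fluct)
  }
}

#' Local exposure time of a scanned beam
#'
#' Time a given point is illuminated as the scanned light sheet passes:
#' beam width divided by the scan speed relative to the flowing cells.
#' 26 µm at 2.54 m/s gives ~10 µs; the blur-free limit without motion
#' cancellation is one pixel over the flow speed, 0.325 µm at 1 m/s ≈ 0.3 µs.
#'
#' @param beam_width beam width \[µm\].
#' @param relative_scan_speed scan speed relative to the cells \[m/s\].
#' @return local exposure time \[µs\].
#' @export
local_exposure_time <- function(beam_width, relative_scan_speed) {
  check_positive(beam_width = beam_width, relative_scan_speed = relative_scan_speed)
  beam_width / relative_scan_speed
}

#' Acquisition-modality preset for SNR comparison
#'
#' Encodes how the per-molecule illumination time depends on flow speed and
#' geometry for each modality, together with sensor noise characteristics:
#' \describe{
#'   \item{viffi}{motion-cancelled: full camera exposure (default 340 µs),
#'     with a 10% signal derating for the extra scanner/relay losses in
#'     excitation and image formation.}
#'   \item{tdi}{time-delay-integration CCD: integration over `n_tdi_rows`
#'     line times at line rate `v/p_x`, infeasible above the readout-limited
#'     maximum line rate.}
#'   \item{stroboscopic}{blur-free strobe: one pixel crossing time `p_x/v`.}
#' }
#' Default noise values are documented estimates for a modern sCMOS
#' (`eta_sensor` 0.6, `sigma_read` 2 e-) and a TDI-CCD (`eta_sensor` 0.6,
#' `sigma_read` 30 e-, i.e. tens of photoelectrons); all are overridable.
#'
#' @param name one of `"viffi"`, `"tdi"`, `"stroboscopic"`.
#' @param eta_sensor sensor quantum efficiency.
#' @param sigma_read readout noise \[electrons RMS\].
#' @param derating multiplicative efficiency derating on the signal.
#' @param exposure_us fixed camera exposure for `viffi` \[µs\].
#' @param max_line_rate readout-limited maximum line rate \[Hz\] (`tdi` only).
#' @param n_tdi_rows number of TDI integration stages (`tdi` only; nominal 256).
#' @return object of class `viffi_modality`.
#' @export
modality_preset <- function(name = c("viffi", "tdi", "stroboscopic"),
                            eta_sensor = NULL, sigma_read = NULL,
                            derating = NULL, exposure_us = 340,
                            max_line_rate = 0.12e6, n_tdi_rows = 256) {
  name <- match.arg(name)
  defaults <- switch(name,
    viffi = list(eta_sensor = 0.6, sigma_read = 2, derating = 0.9),
    tdi = list(eta_sensor = 0.6, sigma_read = 30, derating = 1),
    stroboscopic = list(eta_sensor = 0.6, sigma_read = 2, derating = 1))
  out <- list(name = name,
              eta_sensor = if (is.null(eta_sensor)) defaults$eta_sensor else eta_sensor,
              sigma_read = if (is.null(sigma_read)) defaults$sigma_read else sigma_read,
              derating = if (is.null(derating)) defaults$derating else derating,
              exposure_us = exposure_us,
              max_line_rate = max_line_rate,
              n_tdi_rows = n_tdi_rows)
  class(out) <- "viffi_modality"
  out
}

#' Default set of the three comparison modalities
#' @return named list of [modality_preset()]s.
#' @export
modality_presets <- function() {
  list(viffi = modality_preset("viffi"),
       tdi = modality_preset("tdi"),
       stroboscopic = modality_preset("stroboscopic"))
}

# internal: per-molecule illumination time [s] for a preset at flow speed v
modality_illumination_time <- function(preset, v, p_x) {
  switch(preset$name,
    viffi = preset$exposure_us * 1e-6,
    stroboscopic = p_x * 1e-6 / v,
    tdi = preset$n_tdi_rows * p_x * 1e-6 / v)
}

#' Compare modalities on an SNR surface
#'
#' For each (modality, flow speed, molecules-per-pixel) grid point, derives
#' the illumination time from the preset's exposure rule, the signal from the
#' product signal model, and the SNR under shot plus readout noise. TDI rows
#' whose required line rate `v/p_x` exceeds the readout cap are flagged
#' infeasible (SNR reported as `NA`).
#'
#' @param presets list of [modality_preset()]s.
#' @param v_grid flow speeds \[m/s\].
#' @param n_grid numbers of fluorescent molecules per pixel area.
#' @param budget baseline [photon_budget()] shared by all modalities;
#'   its `T_illum`, `n`, `eta_sensor` and `sigma_read` entries are overridden
#'   per grid point / preset.
#' @param p_x object-plane pixel size \[µm\].
#' @return data.frame with columns `modality`, `v_m_per_s`, `n_per_pixel`,
#'   `T_us`, `S_electrons`, `snr`, `feasible`.
#' @export
compare_modalities <- function(presets, v_grid, n_grid,
                               budget = photon_budget(P = 1e6), p_x = 0.325) {
  stopifnot(all(vapply(presets, inherits, logical(1), "viffi_modality")))
  grid <- expand.grid(pi_ = seq_along(presets), v = v_grid, n = n_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    preset <- presets[[grid$pi_[i]]]
    v <- grid$v[i]; n <- grid$n[i]
    feasible <- !(preset$name == "tdi" &&
                    v / (p_x * 1e-6) > preset$max_line_rate)
    t_ill <- modality_illumination_time(preset, v, p_x)
    b <- budget
    b$T_illum <- t_ill
    b$n <- n
    b$eta_sensor <- preset$eta_sensor
    s_el <- signal_electrons(b) * preset$derating
    data.frame(modality = preset$name, v_m_per_s = v, n_per_pixel = n,
               T_us = t_ill * 1e6, S_electrons = s_el,
               snr = if (feasible) snr(s_el, preset$sigma_read) else NA_real_,
               feasible = feasible)
  })
  do.call(rbind, rows)
}
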