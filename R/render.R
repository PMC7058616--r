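#' Acquisition mode
#'
#' The three acquisition modes compared throughout:
#' `NO_VIFFI_SHORT` (blur-free short exposure, uniform illumination),
#' `NO_VIFFI_LONG` (long exposure without motion cancellation: streaks), and
#' `VIFFI` (motion cancellation plus scanned light-sheet excitation).
#' `VIFFI` requires `beam_scan = TRUE`.
#'
#' @param name mode name.
#' @param exposure_us camera exposure \[µs\].
#' @param beam_scan logical; scanned light-sheet excitation?
#' @param beam_width excitation beam e^-2 full width in the flow direction \[µm\].
#' @param relative_scan_speed beam scan speed relative to the cells \[m/s\].
#' @return object of class `viffi_mode`.
#' @export
acquisition_mode <- function(name = c("VIFFI", "NO_VIFFI_SHORT", "NO_VIFFI_LONG"),
                             exposure_us = NULL, beam_scan = NULL,
                             beam_width = 26, relative_scan_speed = 2.54) {
  name <- match.arg(name)
  defaults <- switch(name,
    NO_VIFFI_SHORT = list(exposure_us = 0.3, beam_scan = FALSE),
    NO_VIFFI_LONG = list(exposure_us = 340, beam_scan = FALSE),
    VIFFI = list(exposure_us = 340, beam_scan = TRUE))
  exposure_us <- if (is.null(exposure_us)) defaults$exposure_us else exposure_us
  beam_scan <- if (is.null(beam_scan)) defaults$beam_scan else beam_scan
  check_positive(exposure_us = exposure_us, beam_width = beam_width,
                 relative_scan_speed = relative_scan_speed)
  if (name == "VIFFI" && !beam_scan) {
    stop("VIFFI mode requires 'beam_scan = TRUE'", call. = FALSE)
  }
  structure(list(name = name, exposure_us = exposure_us, beam_scan = beam_scan,
                 beam_width = beam_width,
                 relative_scan_speed = relative_scan_speed),
            class = "viffi_mode")
}

#' Sensor noise model
#'
#' Photon detection (quantum efficiency), Poisson shot noise, Gaussian readout
#' noise, linear gain/offset and 16-bit quantization. Defaults describe an
#' sCMOS sensor.
#'
#' @param eta_sensor quantum efficiency (0..1).
#' @param sigma_read readout noise \[electrons RMS\].
#' @param gain conversion gain \[electrons per digital number\].
#' @param offset digital offset \[DN\].
#' @param bit_depth output bit depth (values clamped to `2^bit_depth - 1`).
#' @return object of class `viffi_noise`.
#' @export
sensor_noise <- function(eta_sensor = 0.6, sigma_read = 2, gain = 1,
                         offset = 100, bit_depth = 16) {
  if (eta_sensor < 0 || eta_sensor > 1) stop("'eta_sensor' in [0,1]", call. = FALSE)
  if (sigma_read < 0) stop("'sigma_read' must be >= 0", call. = FALSE)
  check_positive(gain = gain)
  structure(list(eta_sensor = eta_sensor, sigma_read = sigma_read, gain = gain,
                 offset = offset, bit_depth = as.integer(bit_depth)),
            class = "viffi_noise")
}

#' Residual image-motion speed across the field of view
#'
#' After polygon cancellation, image distortion leaves a position-dependent
#' residual image-motion speed. Only its range is characterized (±1.5% of the
#' flow speed with the beam scan, at least ±6% without), so the spatial
#' structure is modelled as an odd-symmetric linear ramp across the FOV: zero
#' at the center, the signed bound at the edges. The ramp amplitudes are
#' parameterizable.
#'
#' @param x object-plane position(s) along the flow \[µm\], within
#'   \[0, FOV_x\].
#' @param design a [viffi_design()].
#' @param beam_scan logical; with (`TRUE`, ±1.5%) or without (`FALSE`, ±6%)
#'   the excitation beam scan.
#' @param amp_on,amp_off ramp amplitude at the FOV edge for the two cases.
#' @return residual speed as a signed fraction of the flow speed.
#' @export
residual_speed_profile <- function(x, design, beam_scan = TRUE,
                                   amp_on = 0.015, amp_off = 0.06) {
  stopifnot(inherits(design, "viffi_design"))
  fx <- fov_x(design)
  if (any(x < -1e-9 | x > fx + 1e-9)) {
    stop("'x' must lie within the field of view [0, FOV_x]", call. = FALSE)
  }
  amp <- if (beam_scan) amp_on else amp_off
  amp * (x - fx / 2) / (fx / 2)
}

# internal: Gaussian PSF standard deviation [um] for a given wavelength/NA
psf_sigma_um <- function(lambda_nm = 530, na = 0.75) 0.21 * lambda_nm / 1e3 / na

# internal: blur pad radius for a given PSF sigma [px]
blur_pad <- function(sigma_px) max(1L, ceiling(4 * sigma_px))

# internal: separable Gaussian blur, kernel normalized to unit sum,
# image padded by blur_pad() on every side so total intensity is conserved
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- blur_pad(sigma_px)
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  conv_rows <- function(m) {
    nc <- ncol(m)
    out <- matrix(0, nrow(m), nc + 2 * r)
    for (t in seq_along(k)) {
      out[, (t):(t + nc - 1)] <- out[, (t):(t + nc - 1)] + m * k[t]
    }
    out
  }
  img2 <- conv_rows(img)           # along x (columns)
  img3 <- t(conv_rows(t(img2)))    # along y (rows)
  attr(img3, "pad") <- r
  img3
}

# internal: 1-D motion kernel from time-stepped drift offsets and excitation
# weights. Offsets are deposited at pixel resolution with linear
# interpolation; kernel sum equals total fluence [us-equivalents].
motion_kernel <- function(offsets_px, weights) {
  stopifnot(length(offsets_px) == length(weights))
  if (length(offsets_px) == 0) return(list(taps = 1, origin = 1L))
  lo <- floor(min(offsets_px))
  hi <- ceiling(max(offsets_px))
  taps <- numeric(hi - lo + 2)
  j <- floor(offsets_px)
  frac <- offsets_px - j
  idx <- j - lo + 1L
  for (i in seq_along(idx)) {
    taps[idx[i]] <- taps[idx[i]] + weights[i] * (1 - frac[i])
    taps[idx[i] + 1L] <- taps[idx[i] + 1L] + weights[i] * frac[i]
  }
  list(taps = taps, origin = 1L - lo)  # taps[origin] is zero offset
}

# internal: convolve each row of m with kernel taps along x; returns a wider
# matrix whose column 'j + origin - 1' corresponds to input column j at zero
# offset
conv_x <- function(m, taps) {
  nc <- ncol(m)
  out <- matrix(0, nrow(m), nc + length(taps) - 1)
  for (t in seq_along(taps)) {
    if (taps[t] != 0) {
      out[, t:(t + nc - 1)] <- out[, t:(t + nc - 1)] + m * taps[t]
    }
  }
  out
}

# internal: substep midpoints dividing the exposure exactly (dt shrinks to
# fit, so weights always sum to the exposure). The step is additionally
# refined so the image drifts at most 0.3 px per substep, which keeps the
# sampled trajectory free of comb artifacts.
time_steps <- function(t_exp, dt_us, drift_px_per_us = 0) {
  if (drift_px_per_us > 0) dt_us <- min(dt_us, 0.3 / drift_px_per_us)
  n <- max(1L, ceiling(t_exp / dt_us))
  dt <- t_exp / n
  list(t_k = (seq_len(n) - 0.5) * dt, dt = dt)
}

# internal: excitation time weights [us] for each substep midpoint t_k over
# the exposure. Uniform illumination: dt each. Scanned beam: Gaussian beam of
# e^-2 full width w crossing the FOV at the relative scan speed, with peak
# gain FOV_x/(w_r sqrt(pi/2)) so that total beam power equals the uniform
# case; per-emitter fluence is then FOV_x / v_scan (~327 us at the default
# design).
excitation_weights <- function(t_k, dt, mode, x_emitter, design) {
  if (!mode$beam_scan) return(rep(dt, length(t_k)))
  fx <- fov_x(design)
  w_r <- mode$beam_width / 2                 # e^-2 radius [um]
  v_s <- mode$relative_scan_speed            # um/us
  gain <- fx / (w_r * sqrt(pi / 2))
  t_scan <- fx / v_s
  t0 <- (mode$exposure_us - t_scan) / 2      # center the sweep in the exposure
  x_b <- (t_k - t0) * v_s                    # beam center in frozen frame [um]
  gain * exp(-2 * (x_b - x_emitter)^2 / w_r^2) * dt
}

# internal: apply the sensor model to an expected-photon image
apply_sensor <- function(expected_photons, noise) {
  lambda <- expected_photons * noise$eta_sensor
  e <- numeric(length(lambda))
  small <- lambda < 1000
  e[small] <- stats::rpois(sum(small), lambda[small])
  if (any(!small)) {  # Gaussian approximation for large means
    e[!small] <- round(stats::rnorm(sum(!small), lambda[!small], sqrt(lambda[!small])))
  }
  e <- e + stats::rnorm(length(e), 0, noise$sigma_read)
  dn <- round(e / noise$gain) + noise$offset
  dn <- pmin(pmax(dn, 0), 2^noise$bit_depth - 1)
  matrix(as.integer(dn), nrow(expected_photons), ncol(expected_photons))
}

# internal: add a local window 'w' into image 'img' with its (1,1) at
# (row0, col0) (may be off-frame; clipped)
add_window <- function(img, w, row0, col0) {
  r1 <- max(1L, row0); r2 <- min(nrow(img), row0 + nrow(w) - 1L)
  c1 <- max(1L, col0); c2 <- min(ncol(img), col0 + ncol(w) - 1L)
  if (r1 > r2 || c1 > c2) return(img)
  img[r1:r2, c1:c2] <- img[r1:r2, c1:c2] +
    w[(r1 - row0 + 1L):(r2 - row0 + 1L), (c1 - col0 + 1L):(c2 - col0 + 1L)]
  img
}

# internal: drift velocity of an emitter at x [um] in um/us
drift_velocity <- function(x, speed_fluct, mode, design, residual_args) {
  v <- design$v_flow  # m/s == um/us
  if (mode$name == "VIFFI") {
    (do.call(residual_speed_profile,
             c(list(x = min(max(x, 0), fov_x(design)), design = design,
                    beam_scan = mode$beam_scan), residual_args)) + speed_fluct) * v
  } else {
    (1 + speed_fluct) * v
  }
}

#' Render one camera frame of a flowing scene
#'
#' Physics-based image formation: every emitter's image-plane trajectory is
#' integrated over the exposure in `dt_us` sub-steps. The object moves at
#' `v (1 + speed_fluct)`; in `VIFFI` mode the polygon cancellation subtracts
#' the nominal speed, leaving the residual drift
#' `(residual_speed_profile + speed_fluct) v`; in the other modes the full
#' flow speed drifts the image. The excitation weight at each instant is a
#' Gaussian light-sheet profile centered on the scanned beam position (or
#' uniform when the beam scan is off). Emitted photons are convolved with a
#' Gaussian PSF (`sigma = 0.21 lambda / NA`), then photon counts are drawn
#' Poisson (Gaussian approximation above mean 1000), scaled by the quantum
#' efficiency, readout noise is added and the result is quantized to 16 bits.
#'
#' Extended structures (nucleus, cytoplasm, droplets) are rendered by
#' rasterizing the static cell, blurring with the PSF, and convolving along
#' the flow axis with the cell's motion kernel (exact for drift that is
#' uniform across one cell, which holds to ~1e-4); beads are rendered by
#' direct per-substep Gaussian splats. Emitters leaving the FOV mid-exposure
#' are clipped, not errors.
#'
#' Channels are rendered to disjoint halves of one frame (dichroic split):
#' rows `1..n_y` are channel 1, rows `n_y+1..2 n_y` channel 2.
#'
#' @param scene a [generate_scene()] or `viffi_scene`.
#' @param mode an [acquisition_mode()].
#' @param design a [viffi_design()].
#' @param noise a [sensor_noise()], or `NULL` to return the noiseless
#'   expected-photon image.
#' @param seed RNG seed for the photon noise.
#' @param n_x,n_y frame size in pixels; defaults cover the scene extent
#'   (capped at the design FOV) and the design's `N_y`.
#' @param photon_scale global scale from fluorophore density to photons
#'   \[photons per molecule per µs of uniform-equivalent fluence\]; the
#'   absolute calibration is a free parameter of the simulator.
#' @param dt_us time sub-step \[µs\] (default 0.5, fine enough to resolve the
#'   ~10-µs local illumination window).
#' @param lambda_nm,na emission wavelength and numerical aperture for the PSF.
#' @param motion logical; set `FALSE` to freeze all motion (static render).
#' @param residual_args extra arguments passed to [residual_speed_profile()].
#' @return object of class `viffi_frame`: list with `data` (integer matrix
#'   `2 n_y x n_x`, or expected photons if `noise = NULL`), `pixel_size`
#'   \[µm\], `mode`, `seed`, `layout`, and `truth` (bead ground truth).
#' @export
render_frame <- function(scene, mode, design, noise = sensor_noise(), seed = 1,
                         n_x = NULL, n_y = NULL, photon_scale = 1,
                         dt_us = 0.5, lambda_nm = 530, na = 0.75,
                         motion = TRUE, residual_args = list()) {
  stopifnot(inherits(scene, "viffi_scene"), inherits(mode, "viffi_mode"),
            inherits(design, "viffi_design"))
  set.seed(as.integer(seed))
  p <- pixel_size(design)
  if (is.null(n_x)) n_x <- min(ceiling(scene$extent / p), round(fov_x(design) / p))
  if (is.null(n_y)) n_y <- design$N_y
  sig_px <- psf_sigma_um(lambda_nm, na) / p
  channels <- list(matrix(0, n_y, n_x), matrix(0, n_y, n_x))

  for (cell in scene$cells) {
    ch_imgs <- render_cell_window(cell, mode, design, p, sig_px, dt_us,
                                  photon_scale, motion, residual_args)
    for (ci in 1:2) {
      if (!is.null(ch_imgs$windows[[ci]])) {
        channels[[ci]] <- add_window(channels[[ci]], ch_imgs$windows[[ci]],
                                     ch_imgs$row0, ch_imgs$col0)
      }
    }
    if (!is.null(cell$droplets) && nrow(cell$droplets) > 0) {
      # droplets: drifting point emitters with the disk's second moment
      # (variance r^2/4 per axis) folded into the PSF width
      for (k in seq_len(nrow(cell$droplets))) {
        d <- cell$droplets[k, ]
        sig_d <- sqrt(sig_px^2 + (d$radius / (2 * p))^2)
        sp <- splat_point(d$x, d$y, d$density * pi * d$radius^2 * photon_scale,
                          cell$speed_fluct, mode, design, p, sig_d,
                          dt_us, motion, residual_args)
        channels[[cell$droplet_channel]] <-
          add_window(channels[[cell$droplet_channel]], sp$w, sp$row0, sp$col0)
      }
    }
  }

  if (nrow(scene$beads) > 0) {
    for (i in seq_len(nrow(scene$beads))) {
      b <- scene$beads[i, ]
      sp <- splat_point(b$x, b$y, b$rate * photon_scale, 0, mode, design, p,
                        sig_px, dt_us, motion, residual_args)
      channels[[1]] <- add_window(channels[[1]], sp$w, sp$row0, sp$col0)
    }
  }

  data <- rbind(channels[[1]], channels[[2]])
  if (!is.null(noise)) data <- apply_sensor(data, noise)
  structure(list(data = data, pixel_size = p, mode = mode$name, seed = as.integer(seed),
                 layout = list(n_channels = 2L, n_y = as.integer(n_y),
                               y_offsets = c(0L, as.integer(n_y)), x_shift = 0L),
                 truth = scene$beads),
            class = "viffi_frame")
}

# internal: static raster + PSF blur + motion kernel for one cell's extended
# structures (nucleus + cytoplasm); droplets are splatted separately as point
# emitters. Returns per-channel local windows and 1-based frame placement.
render_cell_window <- function(cell, mode, design, p, sig_px, dt_us,
                               photon_scale, motion, residual_args) {
  pad_um <- 2
  x0 <- min(cell$lobes$x - cell$lobes$r, cell$center[1] - cell$cell_radius) - pad_um
  x1 <- max(cell$lobes$x + cell$lobes$r, cell$center[1] + cell$cell_radius) + pad_um
  y0 <- cell$center[2] - cell$cell_radius - pad_um
  y1 <- cell$center[2] + cell$cell_radius + pad_um
  c0 <- floor(x0 / p); c1 <- ceiling(x1 / p)
  r0 <- floor(y0 / p); r1 <- ceiling(y1 / p)
  nxl <- c1 - c0 + 1L; nyl <- r1 - r0 + 1L
  # pixel-center coordinates of the local window [um] (0-based pixel j has
  # center (j + 0.5) p)
  xc <- (c0:c1 + 0.5) * p
  yc <- (r0:r1 + 0.5) * p
  dist2 <- function(cx, cy) outer((yc - cy)^2, (xc - cx)^2, `+`)

  rasters <- list(matrix(0, nyl, nxl), matrix(0, nyl, nxl))
  if (cell$nucleus_density > 0) {  # nucleus: union of lobes
    inside <- matrix(FALSE, nyl, nxl)
    for (k in seq_len(nrow(cell$lobes))) {
      inside <- inside | dist2(cell$lobes$x[k], cell$lobes$y[k]) <= cell$lobes$r[k]^2
    }
    rasters[[cell$nucleus_channel]] <- rasters[[cell$nucleus_channel]] +
      inside * cell$nucleus_density * p^2
  }
  if (cell$cytoplasm_density > 0) {
    inside <- dist2(cell$center[1], cell$center[2]) <= cell$cell_radius^2
    rasters[[cell$cytoplasm_channel]] <- rasters[[cell$cytoplasm_channel]] +
      inside * cell$cytoplasm_density * p^2
  }

  # excitation fluence and motion kernel evaluated at the cell center (drift
  # and beam-passage timing vary negligibly across one cell)
  v_d <- if (motion) {
    drift_velocity(cell$center[1], cell$speed_fluct, mode, design, residual_args)
  } else 0
  tt <- time_steps(mode$exposure_us, dt_us, abs(v_d) / p)
  w_t <- excitation_weights(tt$t_k, tt$dt, mode, cell$center[1], design)
  fluence <- sum(w_t)
  offs_px <- v_d * (tt$t_k - mode$exposure_us / 2) / p
  mk <- motion_kernel(offs_px, w_t / max(fluence, .Machine$double.eps))

  padb <- blur_pad(sig_px)
  windows <- list(NULL, NULL)
  for (ci in 1:2) {
    if (all(rasters[[ci]] == 0)) next
    blurred <- gaussian_blur(rasters[[ci]], sig_px)
    windows[[ci]] <- conv_x(blurred, mk$taps) * fluence * photon_scale
  }
  # window row 1 is frame row (r0 - padb) 0-based; window col 1 corresponds
  # to 0-based frame column (c0 - padb) shifted by (1 - origin) kernel taps
  list(windows = windows,
       row0 = r0 - padb + 1L,
       col0 = c0 - padb - (mk$origin - 1L) + 1L)
}

# internal: time-integrated splat of a drifting point emitter
splat_point <- function(x, y, rate, speed_fluct, mode, design, p, sig_px,
                        dt_us, motion, residual_args) {
  v_d <- if (motion) drift_velocity(x, speed_fluct, mode, design, residual_args) else 0
  tt <- time_steps(mode$exposure_us, dt_us, abs(v_d) / p)
  w_t <- excitation_weights(tt$t_k, tt$dt, mode, x, design)
  keep <- w_t > max(w_t) * 1e-8
  w_t <- w_t[keep]
  tk <- tt$t_k[keep]
  xs <- x + v_d * (tk - mode$exposure_us / 2)   # um
  cx <- xs / p - 0.5
  cy <- y / p - 0.5
  r <- max(2L, ceiling(5 * sig_px))
  cols <- (floor(min(cx)) - r):(floor(max(cx)) + r)
  rows <- (floor(cy) - r):(floor(cy) + r)
  gy <- stats::dnorm(rows, cy, sig_px)
  gy <- gy / sum(gy)
  vx <- numeric(length(cols))
  for (i in seq_along(tk)) {
    gx <- stats::dnorm(cols, cx[i], sig_px)
    vx <- vx + w_t[i] * gx / sum(gx)
  }
  list(w = (gy %o% vx) * rate, row0 = rows[1] + 1L, col0 = cols[1] + 1L)
}

#' Render a field of calibration beads
#'
#' Sub-resolution point emitters (200-nm-bead analogues) at uniformly random
#' sub-pixel positions, rendered under a given acquisition mode, with the
#' ground-truth positions returned for fitting validation.
#'
#' @param n_beads number of beads (>= 1).
#' @param design a [viffi_design()].
#' @param mode an [acquisition_mode()].
#' @param noise a [sensor_noise()] or `NULL` for noiseless output.
#' @param seed RNG seed.
#' @param n_x,n_y frame size \[px\]; defaults to the design FOV and `N_y`.
#' @param bead_rate emission rate \[photons/µs of uniform-equivalent fluence\].
#' @param margin_px margin kept free of beads at the frame edges.
#' @param speed_fluct_sd,speed_fluct_bound per-bead flow-speed fluctuation
#'   (as for cells).
#' @param ... further arguments to [render_frame()]'s internals
#'   (`photon_scale`, `dt_us`, `lambda_nm`, `na`, `motion`, `residual_args`).
#' @return a `viffi_frame` whose `truth` is a data.frame of bead positions
#'   (`x`, `y` \[µm\], `rate`, `speed_fluct`).
#' @export
render_bead_field <- function(n_beads, design, mode, noise = sensor_noise(),
                              seed = 1, n_x = NULL, n_y = NULL,
                              bead_rate = 200, margin_px = 12,
                              speed_fluct_sd = 0.0075,
                              speed_fluct_bound = 0.015, ...) {
  stopifnot(n_beads >= 1)
  set.seed(as.integer(seed))
  p <- pixel_size(design)
  if (is.null(n_x)) n_x <- round(fov_x(design) / p)
  if (is.null(n_y)) n_y <- design$N_y
  truth <- data.frame(
    x = stats::runif(n_beads, margin_px * p, (n_x - margin_px) * p),
    y = stats::runif(n_beads, margin_px * p, (n_y - margin_px) * p),
    rate = bead_rate,
    speed_fluct = truncated_normal(n_beads, speed_fluct_sd, speed_fluct_bound))
  scene <- structure(list(cells = list(), beads = truth[, c("x", "y", "rate")],
                          extent = n_x * p, seed = as.integer(seed)),
                     class = "viffi_scene")
  fr <- render_frame_beads(scene, truth, mode, design, noise, seed, n_x, n_y, ...)
  fr$truth <- truth
  fr
}

# internal: like render_frame but with per-bead speed fluctuations
render_frame_beads <- function(scene, truth, mode, design, noise, seed, n_x, n_y,
                               photon_scale = 1, dt_us = 0.5, lambda_nm = 530,
                               na = 0.75, motion = TRUE, residual_args = list()) {
  set.seed(as.integer(seed) + 1L)
  p <- pixel_size(design)
  sig_px <- psf_sigma_um(lambda_nm, na) / p
  ch1 <- matrix(0, n_y, n_x)
  for (i in seq_len(nrow(truth))) {
    sp <- splat_point(truth$x[i], truth$y[i], truth$rate[i] * photon_scale,
                      truth$speed_fluct[i], mode, design, p, sig_px,
                      dt_us, motion, residual_args)
    ch1 <- add_window(ch1, sp$w, sp$row0, sp$col0)
  }
  data <- rbind(ch1, matrix(0, n_y, n_x))
  if (!is.null(noise)) data <- apply_sensor(data, noise)
  structure(list(data = data, pixel_size = p, mode = mode$name,
                 seed = as.integer(seed),
                 layout = list(n_channels = 2L, n_y = as.integer(n_y),
                               y_offsets = c(0L, as.integer(n_y)), x_shift = 0L),
                 truth = truth),
            class = "viffi_frame")
}
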