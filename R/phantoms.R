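#' Cell phantom: ground-truth flowing object
#'
#' Geometric description of one fluorescent cell used by the image-formation
#' simulator: a nucleus (single disk, or a lobulated union of `n_lobes`
#' overlapping disks as in neutrophil-like cells), a cytoplasm disk, and
#' optional sub-micron lipid droplets, each with a fluorophore surface density
#' and a color channel. `speed_fluct` is the cell's own fractional deviation
#' from the nominal flow speed (the cell-to-cell component of the ~1.5% flow
#' fluctuation).
#'
#' @param center numeric length-2, cell center (x, y) \[µm\]; x is the flow
#'   direction.
#' @param cell_radius cell radius \[µm\].
#' @param nucleus_type `"disk"` or `"lobed"`.
#' @param n_lobes number of nuclear lobes (1..5) when `nucleus_type = "lobed"`.
#' @param nucleus_radius overall nucleus radius \[µm\].
#' @param nucleus_density nuclear fluorophore density \[molecules/µm²\].
#' @param nucleus_channel channel index of the nuclear stain.
#' @param cytoplasm_density cytoplasm fluorophore density \[molecules/µm²\].
#' @param cytoplasm_channel channel index of the cytoplasm stain.
#' @param droplets `NULL` or data.frame with columns `x`, `y` (\[µm\],
#'   absolute), `radius` (\[µm\], 0.3–1.5), `density`.
#' @param droplet_channel channel index of the droplet stain.
#' @param speed_fluct fractional flow-speed deviation of this cell.
#' @param lobe_angle orientation of the first lobe \[radians\].
#' @return object of class `viffi_phantom`.
#' @export
cell_phantom <- function(center, cell_radius = 5, nucleus_type = c("disk", "lobed"),
                         n_lobes = 3, nucleus_radius = 3,
                         nucleus_density = 100, nucleus_channel = 1L,
                         cytoplasm_density = 30, cytoplasm_channel = 2L,
                         droplets = NULL, droplet_channel = 1L,
                         speed_fluct = 0, lobe_angle = 0) {
  nucleus_type <- match.arg(nucleus_type)
  stopifnot(length(center) == 2, is.finite(center))
  check_positive(cell_radius = cell_radius)
  if (nucleus_type == "lobed" && (n_lobes < 1 || n_lobes > 5)) {
    stop("'n_lobes' must be in 1..5", call. = FALSE)
  }
  if (nucleus_density < 0 || cytoplasm_density < 0) {
    stop("densities must be >= 0", call. = FALSE)
  }
  if (!is.null(droplets)) {
    stopifnot(is.data.frame(droplets),
              all(c("x", "y", "radius", "density") %in% names(droplets)))
    if (any(droplets$density < 0)) stop("droplet densities must be >= 0", call. = FALSE)
    dd <- sqrt((droplets$x - center[1])^2 + (droplets$y - center[2])^2)
    if (any(dd + droplets$radius > cell_radius + 1e-9)) {
      stop("droplets must lie inside the cell radius", call. = FALSE)
    }
  }
  # lobes: n_lobes disks of radius r_l placed on a ring so their union spans
  # roughly 'nucleus_radius'
  lobes <- if (nucleus_type == "disk" || n_lobes == 1) {
    data.frame(x = center[1], y = center[2], r = nucleus_radius)
  } else {
    r_l <- nucleus_radius * 0.55
    off <- nucleus_radius - r_l
    ang <- lobe_angle + 2 * pi * (seq_len(n_lobes) - 1) / n_lobes
    data.frame(x = center[1] + off * cos(ang), y = center[2] + off * sin(ang),
               r = r_l)
  }
  structure(list(center = center, cell_radius = cell_radius,
                 nucleus_type = nucleus_type, n_lobes = as.integer(n_lobes),
                 nucleus_radius = nucleus_radius, lobes = lobes,
                 nucleus_density = nucleus_density,
                 nucleus_channel = as.integer(nucleus_channel),
                 cytoplasm_density = cytoplasm_density,
                 cytoplasm_channel = as.integer(cytoplasm_channel),
                 droplets = droplets, droplet_channel = as.integer(droplet_channel),
                 speed_fluct = speed_fluct),
            class = "viffi_phantom")
}

#' Generate a random flowing scene
#'
#' Cells are laid out along the flow axis as a Poisson line process:
#' consecutive spacings are i.i.d. exponential with the given mean (cells in
#' suspension arrive at random, so the count in any window is Poisson). The
#' default mean spacing of 75 µm sits inside the 50–100 µm operating range
#' that, at 1 m/s, corresponds to >10,000 cells/s. Cell-to-cell flow-speed
#' fluctuations are Gaussian with `speed_fluct_sd`, truncated at
#' `speed_fluct_bound` (±1.5% by default). Reproducible for a fixed seed.
#'
#' @param extent scene length along the flow direction \[µm\].
#' @param mean_spacing mean cell spacing \[µm\].
#' @param seed RNG seed (integer).
#' @param y_center,y_jitter cross-flow placement: cells at
#'   `y_center + U(-y_jitter, y_jitter)` \[µm\] (hydrodynamically focused core).
#' @param speed_fluct_sd,speed_fluct_bound Gaussian sd and truncation bound of
#'   the per-cell fractional speed deviation.
#' @param cell_generator function `(id, center, speed_fluct) -> viffi_phantom`;
#'   default makes round-nucleus two-channel cells with a few droplets.
#' @param n_beads number of point-emitter beads to scatter uniformly
#'   (default 0).
#' @param bead_rate bead emission rate \[photons/µs of uniform-equivalent
#'   fluence\].
#' @return object of class `viffi_scene`: list with `cells` (list of
#'   phantoms), `beads` (data.frame x, y, rate), `extent`, `seed`.
#' @export
generate_scene <- function(extent = 2000, mean_spacing = 75, seed = 1,
                           y_center = 14.3, y_jitter = 5,
                           speed_fluct_sd = 0.0075, speed_fluct_bound = 0.015,
                           cell_generator = NULL, n_beads = 0,
                           bead_rate = 200) {
  check_positive(extent = extent, mean_spacing = mean_spacing)
  set.seed(as.integer(seed))
  if (is.null(cell_generator)) {
    cell_generator <- function(id, center, speed_fluct) {
      cell_phantom(center, cell_radius = 5, nucleus_type = "disk",
                   nucleus_radius = 3, speed_fluct = speed_fluct)
    }
  }
  # Poisson line process along x; keep margin of one cell radius at the ends
  xs <- c()
  x <- stats::rexp(1, 1 / mean_spacing)
  while (x < extent) {
    xs <- c(xs, x)
    x <- x + stats::rexp(1, 1 / mean_spacing)
  }
  cells <- list()
  for (i in seq_along(xs)) {
    sf <- truncated_normal(1, sd = speed_fluct_sd, bound = speed_fluct_bound)
    ctr <- c(xs[i], y_center + stats::runif(1, -y_jitter, y_jitter))
    cells[[i]] <- cell_generator(i, ctr, sf)
  }
  beads <- if (n_beads > 0) {
    data.frame(x = stats::runif(n_beads, 0, extent),
               y = y_center + stats::runif(n_beads, -y_jitter, y_jitter),
               rate = bead_rate)
  } else {
    data.frame(x = numeric(0), y = numeric(0), rate = numeric(0))
  }
  structure(list(cells = cells, beads = beads, extent = extent,
                 seed = as.integer(seed)),
            class = "viffi_scene")
}

# internal: Gaussian truncated at +/- bound (resampling)
truncated_normal <- function(n, sd, bound) {
  out <- stats::rnorm(n, 0, sd)
  bad <- abs(out) > bound
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(out) > bound
  }
  out
}

#' @export
print.viffi_scene <- function(x, ...) {
  cat(sprintf("<viffi_scene> %d cells, %d beads over %g um (seed %d)\n",
              length(x$cells), nrow(x$beads), x$extent, x$seed))
  invisible(x)
}
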