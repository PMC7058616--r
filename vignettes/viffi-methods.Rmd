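---
title: "Models and methods behind the viffi toolkit"
author: "viffi authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the viffi toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viffi)
```

## The problem

Imaging flow cytometry trades throughput, sensitivity and spatial resolution
against each other: at a flow speed $v$ and object-plane pixel size $p_x$,
a blur-free exposure is limited to the pixel crossing time $p_x/v$
(about 0.3 µs at 1 m/s and 325-nm pixels), which starves the image of
photons. Virtual-freezing fluorescence imaging (VIFFI) breaks the trade-off
by cancelling the image motion with a polygon scanner rotating against the
flow, and by sweeping a confined light-sheet excitation beam across the
field of view so each point is only illuminated for ~10 µs while the camera
integrates for ~340 µs. This package implements the design calculus, the
signal models, an image-formation simulator, and the downstream per-cell
image analysis for this class of instrument.

## Optical design constraints

The scan range a polygon facet can sweep before the fluorescence beam
footprint walks off the facet, referred to the object plane, is

$$L_\mathrm{max} = 4 f_o M \left\{ \frac{2\pi}{N}
 + \arcsin\!\left[\left(-\frac{d_o M}{d_p} + \sin\alpha\right)\cos\frac{\pi}{N}\right]
 - \arcsin\!\left[\left(\frac{d_o M}{d_p} + \sin\alpha\right)\cos\frac{\pi}{N}\right]\right\},$$

with $f_o$ the objective focal length, $M$ the first relay magnification,
$N$ the facet count, $d_o$ the objective back aperture, $d_p$ the polygon
inner diameter and $\alpha$ the nominal incidence angle. `max_scan_range()`
evaluates this and raises a domain error when an arcsine argument leaves
$[-1, 1]$ (a geometrically infeasible design). At the packaged operating
point ($f_o$ = 9 mm, $M$ = 0.2, $N$ = 28, $d_o$ = 13.5 mm, $d_p$ = 70 mm,
$\alpha$ = 45°) it gives 838 µm.

```{r design}
d <- viffi_design()
max_scan_range(d)
max_exposure_from_scan(d)
magnification_bounds(d)
```

**The factor two in the exposure cap.** Because the camera's field of view
co-moves with the flow during the exposure, the usable sweep is traversed at
twice the flow speed; we therefore define the exposure cap as
$L_\mathrm{max}/(2v)$, which reproduces the quoted 420-µs limit at 1 m/s to
the nearest 10 µs. The feasible relay-magnification window
$vT_sN/(4\pi f_o) < M < L_xN/(4\pi f_t)$ evaluates to (0.198, 0.205) and
contains the chosen 0.2.

**Facet fit.** The facet width of a polygon of inner (inscribed-circle)
diameter $d_p$ is taken as $d_p\tan(\pi/N)$; the design constraint is only
qualitative ("footprint smaller than the facet"), so the margin is reported
alongside the pass flag.

**Timing.** Line-wise sCMOS readout takes $L_x N_y/(f_p d_\mathrm{pix})$
(393 µs for 88 lines), and readout plus exposure must fit in the 0.8-ms
frame period. `timing_budget()` reports each constraint by name and never
clamps.

**Frame overlap.** The frame-to-frame overlap $l_0$ is not printed anywhere
we could find; we derive 30 µm from the consistency requirement
$(\mathrm{FOV}_x - l_0)/v = T_s$ at the operating point
(830 µm − 30 µm at 1 m/s = 800 µs) and expose it as the `l_overlap`
parameter.

**FOV vs speed solver.** `fov_y_vs_speed()` inverts the frame equation
$(L_x/M - l_0)/v \approx L_x N_y/(f_p d_\mathrm{pix}) + t_{exp1}$ for the
largest integer $N_y$ leaving at least a minimum exposure, breaking ties
downward (conservative FOV). Note that the operating point ($N_y = 88$ at
1 m/s) corresponds to a minimum exposure of 407 µs — the data-transfer cap
$t_{exp1}$ — not the 340-µs exposure actually used, which sits deliberately
below the cap; the solver recovers 88 lines when asked for 407 µs and 103
lines when asked for 340 µs. Both are self-consistent solutions of the frame
equation; the instrument's margin between 340 and 407 µs absorbs trigger
jitter.

## Flow geometry

Hydrodynamic focusing confines the sample to a core whose diameter follows
from the volumetric flow-rate ratio under an equal-mean-velocity (plug)
approximation: core area = channel area × ratio/(1 + ratio). For the
400 × 250 µm chip at 1:700 this gives ~13 µm (and 5.7 µm at 1:3900, the
setting used for bead calibration). Across that core, the laminar velocity
profile of a rectangular duct (Fourier series solution, truncated at 80 odd
modes with a 10⁻⁶ truncation guard; 80 rather than a smaller count so the
guard is met with margin) varies by under 1%, which is what
makes motion cancellation at a single scanner speed viable.

## Sensitivity model

The per-pixel signal in photoelectrons is the product
$S = P C^{-1} T n s \,\eta_\mathrm{yield}\eta_\mathrm{img}\eta_\mathrm{sensor}$
and the SNR under shot plus readout noise is $S/\sqrt{S + \sigma^2}$.
The improvement calculus: with residual image motion of ±1.5% of the flow
speed (beam scan on) plus a 1.5% cell-to-cell speed fluctuation, exposure
can be extended by $1/(0.015+0.015) \approx 33$; without the beam scan the
residual is at least ±6%, capping the factor at ~13. Confining the
excitation beam to ~3% of the field of view concentrates the same power by
$1/0.03 \approx 33$. Together: $33 \times 33 \approx 1000$ with the scan,
~13 without.

```{r factors}
overall_improvement(d, scan_on = TRUE)
overall_improvement(d, scan_on = FALSE)
local_exposure_time(26, 2.54)   # scanned-beam local exposure [us]
```

**Modality presets.** The exact sensor parameters of the commercial
comparators are not public; the presets ship documented defaults (sCMOS:
quantum efficiency 0.6, read noise 2 e⁻; TDI-CCD: 0.6 and 30 e⁻ — "tens of
photoelectrons"; 256 TDI stages as a nominal value) and every field is
user-overridable. The VIFFI preset carries a single 10% signal derating for
the extra losses at the beam scanner, relay optics and polygon. Because
these defaults are estimates, the package's tests assert only ratio and
limit claims that are robust to them: the TDI line-rate cap (0.12 MHz, i.e.
a ~0.04 m/s speed cap at 325-nm pixels), and the shot-limited VIFFI-to-
stroboscopic SNR ratio at 1 m/s, which is $\sqrt{0.9 \times 340/0.325}
\approx 31 \ge 30$ and can only grow once readout noise is added (the
short-exposure modality is hurt more).

## The image-formation simulator

`render_frame()` integrates each emitter's image-plane trajectory over the
exposure:

- the object moves at $v(1 + \delta_c)$ where $\delta_c$ is the cell's own
  speed deviation, drawn Gaussian with sd 0.75% truncated at ±1.5% (half the
  stated bound as the sd, so the truncation is a tail correction rather than
  a hard clip);
- in VIFFI mode the polygon subtracts the nominal $v$, leaving the residual
  drift $(\rho(x) + \delta_c)v$; the residual profile $\rho(x)$ is modelled
  as an odd linear ramp across the FOV spanning ±1.5% (scan on) or ±6%
  (scan off) — only the range is anchored in measurements, the linear shape
  is our choice and is parameterizable;
- the excitation weight at time $t$ is a Gaussian light sheet of e⁻² full
  width 26 µm crossing the FOV at 2.54 m/s relative to the cells, with peak
  gain $\mathrm{FOV}_x/(w_r\sqrt{\pi/2})$ so the swept beam carries the same
  power as uniform illumination; each emitter then receives
  $\mathrm{FOV}_x/v_\mathrm{scan} \approx 327$ µs of uniform-equivalent
  fluence during a ~10-µs passage;
- emitted photons are blurred with an isotropic Gaussian PSF,
  $\sigma = 0.21\lambda/\mathrm{NA}$ (530 nm, NA 0.75 by default) — the
  instrument's PSF model is not specified beyond its measured widths, so a
  Gaussian is the neutral choice;
- photon counts are Poisson (exact below mean 1000, Gaussian approximation
  above), scaled by the quantum efficiency, readout noise added, quantized
  to 16 bits with a 100-DN offset.

Numerically, extended structures (nucleus, cytoplasm) are rasterized once,
PSF-blurred, and convolved along the flow axis with a per-cell motion kernel
built from 0.5-µs sub-steps; this is exact whenever drift is uniform across
one cell, which holds to ~10⁻⁴ here. Beads and droplets are rendered as
direct per-sub-step Gaussian splats. Sub-steps additionally refine so the
image never drifts more than 0.3 px per step (without this, full-speed
streaks alias into a comb). Time steps divide the exposure exactly, so
photon totals are conserved: with noise and motion disabled, the rendered
total equals the emitted expectation to 10⁻⁶ relative for analytic emitters
(rasterized structures add ~1% area quantization at cell scale).

Two channels share one frame as disjoint row bands (the dichroic split onto
one sensor); `split_channels()` inverts the layout.

**What the phantoms do and do not emulate.** Cells are disks with disk or
lobulated (union of 1–5 disks) nuclei, a cytoplasm disk, and sub-micron
droplet emitters; spacings along the flow are exponential (Poisson arrivals,
75-µm mean by default, inside the 50–100 µm operating range). Cell rotation,
3-D defocus, depth of field and polygon facet-transition artifacts are not
modelled; absolute photon yields per fluorophore are a free scale
(`photon_scale`), so only relative SNR claims are meaningful. Passing
simulator-based tests therefore demonstrates correct image-formation
*kinematics and statistics*, not photometric calibration against the real
instrument.

## Image analysis

- **Segmentation** (`segment()`): Otsu global threshold, closing of radius
  1 px, hole fill, minimum area 20 px — all configurable, since "standard
  segmentation" is underdetermined.
- **Enclosing-box ratio** (`enclosing_box_ratio()`): nucleus area over the
  area of the minimum-area *rotated* enclosing rectangle of the mask's
  pixel-corner set, computed exactly by convex hull + rotating calipers;
  a brute-force 0.1° rotation search guards it in the tests. Whether the
  original analysis used a rotated or axis-aligned box is not stated; the
  rotated box is the literal reading of "smallest area" and is the default
  (`min_area_rect()` is exported for the axis-free primitive). Lobulated
  nuclei score systematically lower than round ones, which is the statistic's
  purpose.
- **Droplet counting** (`count_droplets()`): local maxima in a square window
  matching the droplet size, kept when the peak exceeds the minimum over the
  surrounding annulus (1×–2× the window) by a contrast threshold; plateau
  ties resolve to the plateau centroid. The threshold used for the published
  histograms is not printed, so it is a required parameter.
- **PSF fitting** (`fit_psf()`): 1-D Gaussian-with-offset least squares
  (Levenberg–Marquardt) on the x and y *marginal* profiles of a bead crop —
  marginals use every detected photon, which matters because the
  diffraction-limited spot is undersampled at 325-nm pixels. Width is
  reported as FWe⁻¹M = $2\sqrt{2}\sigma$. Initialization from moments;
  offset bounded below by the profile's 5th percentile; non-convergence is
  flagged on the record rather than thrown.

## Problem sizes and reproducibility

The test suite renders bead fields of ~60 beads per full-width frame (three
frames give the ≥100 isolated beads used for the elongation statistic),
455-µm scenes for streak checks, and 200-cell-per-group phantom populations
for the morphometry statistics — sizes chosen so the whole suite runs in
well under a minute while keeping Monte-Carlo standard errors a factor ≥5
below every asserted margin. All randomness flows through explicit integer
seeds; rendering twice with one seed is bit-identical, and the CLI writes a
manifest (arguments, seed, package version, output checksums) next to every
artifact.

## Known limitations

- The residual-motion spatial profile is a modelling choice (linear ramp);
  real distortion fields are smooth but not linear.
- The simulator's two-channel layout has no chromatic registration error by
  default (`x_shift` in the layout models a rigid shift only).
- The TDI modality is parameterized, not a vendor model; its SNR values are
  only meaningful relative to the other presets.
- Classification (CNN) and embedding analyses are out of scope; the package
  exports per-cell crops and feature tables for external tools instead.
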