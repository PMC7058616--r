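# viffi

Design, simulation and image-analysis toolkit for **virtual-freezing
fluorescence imaging (VIFFI) flow cytometry** — imaging flow cytometry in
which a polygon scanner, rotating against the flow, cancels the image motion
of cells moving at ~1 m/s so the camera can integrate ~1000× longer than the
blur-free limit, while a scanned light-sheet beam confines each cell's local
exposure to ~10 µs. The package is for instrument designers and image
analysts who want to explore this design space, simulate what such an
instrument records, and run the downstream per-cell analysis.

## What it computes

**Optical design.** The polygon scan range referred to the object plane,

L = 4 f_o M { 2π/N + asin[(−d_o M/d_p + sin α) cos(π/N)]
                   − asin[( d_o M/d_p + sin α) cos(π/N)] },

must be positive; the exposure cap is L/(2v) (the field of view co-moves
with the flow, so the sweep is consumed at twice the flow speed). The relay
magnification must satisfy v·T_s·N/(4π f_o) < M < L_x·N/(4π f_t), the beam
footprint d_o·M must fit a facet of width d_p·tan(π/N), and sensor readout
L_x·N_y/(f_p·d_pix) plus exposure must fit the frame period T_s.

**Sensitivity.** Per-pixel signal S = P C⁻¹ T n s η_yield η_img η_sensor
and SNR = S/√(S + σ²); the exposure-extension and beam-confinement factors
(≈33 each, ≈1000 combined with the beam scan, ~13 without); a three-way
modality comparison (motion-cancelled vs TDI-CCD vs stroboscopic).

**Throughput.** Effective line rate v/p_x, cell throughput f_th = p_x f_x /
l_cell, the frame equation (L_x/M − l₀)/v ≈ L_x N_y/(f_p d_pix) + t_exp1 and
its inversion for the field of view attainable at a given flow speed.

**Simulation.** A physics-based renderer of flowing fluorescent cells and
calibration beads under three acquisition modes (blur-free short exposure,
long exposure without cancellation, and full motion cancellation with the
scanned beam), with Gaussian PSF, Poisson shot noise, readout noise and
16-bit quantization. Ground truth is returned for validation.

**Image analysis.** Otsu segmentation, per-cell morphometry, the
nucleus/enclosing-box area ratio (minimum-area rotated rectangle via
rotating calipers — the lobulation statistic), lipid-droplet enumeration by
local-extrema contrast, Gaussian-with-offset PSF fitting (FWe⁻¹M widths),
and CSV/TIFF export of features and CNN-ready crops.

## Worked example

```r
library(viffi)
d <- viffi_design()          # the published operating point
d
#> <viffi_design>
#>   objective f = 9 mm, tube lens f = 180 mm, M_relay = 0.2, M_total = 20x
#>   polygon: 28 facets, inner diameter 70 mm, incidence 45 deg
#>   camera: L_x = 16.6 mm, 6.5 um pixels, 88 lines, 572 MHz pixel rate, T_s = 0.8 ms
#>   flow: 1 m/s; object-plane pixel 0.325 um; FOV 830 x 28.6 um

max_exposure_from_scan(d)    # scan-range exposure cap [us]
#> [1] 419.242                # rounds to the quoted 420 us

timing_budget(d, 340)
#> <viffi_timing>
#>   exposure 340.0 us | readout 392.9 us | scan cap 419.2 us | frame 800 us
#>   exposure_within_scan_cap                340.0 <=    419.2  [ok]
#>   readout_plus_exposure_within_frame      732.9 <=    800.0  [ok]
```

The exposure cap of 419 µs is the longest the polygon can "freeze" a cell;
the budget confirms the 340-µs operating exposure fits the 0.8-ms frame
with the 393-µs readout. Simulating and analyzing a small scene:

```r
sc  <- generate_scene(extent = 300, mean_spacing = 75, seed = 7)
fr  <- render_frame(sc, acquisition_mode("VIFFI"), d, seed = 7,
                    n_x = 930, n_y = 88, photon_scale = 2)
rec <- analyze_frame(fr)
rec[, c("cell_id", "x_um", "area_um2", "nucleus_area_um2", "box_ratio")]
#>   cell_id      x_um area_um2 nucleus_area_um2 box_ratio
#> 1       1   5.19505 79.74688         28.51875 0.7894737
#> 2       2 127.54459 78.58500         28.41313 0.7865497
#> 3       3 254.08273 78.58500         28.09625 0.7777778
```

Three simulated cells (5-µm radius, round 3-µm nuclei) are recovered with
areas near π·5² ≈ 78.5 µm² and box ratios near π/4 ≈ 0.785 — the signature
of a round nucleus; lobulated (neutrophil-like) nuclei score lower.

A command-line entry point wraps the same functions:

```sh
exec/viffi design validate                  # constraint report (JSON)
exec/viffi tradeoff --v 0.1:10:log25 --out tradeoff.csv
exec/viffi simulate --mode VIFFI --seed 7 --out frames/
exec/viffi analyze --in frames/frame_VIFFI_seed7.tif --out features.csv
```

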