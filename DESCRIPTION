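Package: viffi
Title: Design, Simulation and Image Analysis for Virtual-Freezing Fluorescence Imaging Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for virtual-freezing fluorescence imaging (VIFFI) flow
    cytometry, an imaging flow cytometry modality in which a polygon scanner
    cancels the image motion of fast-flowing cells so that a camera can
    integrate roughly a thousand times longer than the blur-free limit.
    Provides the optical-design constraint solver for the polygon scanner and
    relay optics (scan-range and magnification windows, facet fit, acquisition
    timing budget, hydrodynamic-focusing flow geometry), per-pixel
    signal-to-noise models for shot- plus readout-noise limited detection,
    throughput and trade-off calculators between SNR, pixel size, field of
    view and flow speed, a physics-based image-formation simulator of flowing
    fluorescent cells and calibration beads under the different acquisition
    modes, and the downstream image-analysis pipeline: segmentation, nuclear
    morphometry via the minimum-area enclosing rectangle, lipid-droplet
    enumeration by local-extrema contrast, and Gaussian point-spread-function
    characterization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
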