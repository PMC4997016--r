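Package: rafttrack
Title: Single-Particle Tracking Analysis of Lipid Diffusion in Raft-Mimetic Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microsecond-resolution single-particle tracking of
    lipids in phase-separated supported bilayers. Implements time-averaged and
    length-weighted ensemble mean-squared-displacement (MSD) analysis, fitting
    of the anomalous-diffusion model MSD = 4*Gamma*dt^alpha + offset with a
    free dynamic-localization-error offset, microscopic and transient diffusion
    rates, and detection of transient nano-confinements by the
    Simson-Sheets-Jacobson probability-level statistic with Brownian-motion
    null calibration. Includes a synthetic-data generator for trajectories
    (free diffusion, liquid-ordered/liquid-disordered domain partitioning,
    transient trapping in nanoscopic subdomains, localization noise, motion
    blur) and a compact interferometric-scattering (iSCAT) style image chain:
    frame synthesis, temporal-median background removal, 2D Gaussian spot
    localization, and nearest-neighbour trajectory linking.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    nortest,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
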