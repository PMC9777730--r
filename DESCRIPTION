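Package: swehist
Title: Histogram-Based Quantitation of Shear-Wave Elastography Heatmaps
Version: 0.1.0
Authors@R:
    person("Maintainer", "swehist", email = "swehist@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify pseudocolor shear-wave elastography (SWE)
    heatmaps of breast lesions without vendor software. Models the vendor
    colormap as an invertible stiffness-to-color lookup on the 0-180 kPa
    scale, rejects achromatic signal voids, extracts per-channel 250-bin
    RGB histograms with low/high bin-range area-under-curve and skewness
    descriptors, reproduces conventional circular-ROI stiffness metrics
    (SWEavg, SWEmax, SD, Q-box ratio), and evaluates cohorts with
    two-sample Kolmogorov-Smirnov, Mann-Whitney, Kruskal-Wallis with
    Dunn's post-hoc, Shapiro-Wilk, and ROC/Youden analysis. A seeded
    synthetic elastogram simulator replaces clinical images so the whole
    pipeline is testable; a small command-line driver wires simulation,
    feature extraction and cohort comparison together. Reads and writes
    8-bit PNG via a bundled minimal codec (no external imaging library
    required).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
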