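Package: acoustoWMRS
Title: Wavelength-Modulated Raman Monitoring of Acoustically Trapped Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of wavelength-modulated Raman
    spectroscopy (WMRS) time series from acoustically trapped bacterial
    aggregates. Generates modulated Raman spectral series with a
    fingerprint-band catalogue, fluorescence background and shot noise;
    reconstructs background-free differential WMR spectra by per-bin
    regression across excitation steps; quantifies bands by
    zero-crossing and peak-to-valley analysis; classifies per-band time
    trends with Mann-Kendall tests and Theil-Sen slopes; and models the
    acoustic trap physics (radiation force on a small sphere,
    levitation-balance pressure calibration, voltage-to-pressure
    conversion).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'axis.R'
    'catalogue.R'
    'classes-spectra.R'
    'scenario.R'
    'simulate.R'
    'reconstruct.R'
    'peaks.R'
    'trends.R'
    'acoustics.R'
    'io.R'
    'pipeline.R'
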