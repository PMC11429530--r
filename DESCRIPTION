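Package: prestimlink
Title: Prestimulus EEG Spectral PCA, ERP Temporal PCA, and Go/NoGo
    Behaviour Linkage
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for linking prestimulus EEG
    frequency-domain principal components, poststimulus ERP temporal
    principal components, and Go/NoGo task behaviour.  Includes a
    synthetic-data generator with a fully known ground truth (1/f
    background, narrowband oscillators with fixed scalp topographies,
    injected ERP templates, ocular artifacts with known propagation, and
    behaviour carrying planted rank correlations), EDF input/output,
    zero-phase filtering, regression-based ocular artifact correction,
    spherical-spline channel interpolation, automatic artifact rejection,
    corrected prestimulus amplitude spectra (DC-30 Hz at 1 Hz),
    covariance-matrix PCA with Kaiser-normalised Varimax or Promax
    rotation, microvolt-scaled loadings and global mean peak amplitudes,
    and Spearman correlation link tables with Fisher-z confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
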