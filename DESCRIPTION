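Package: escore
Title: Multifrequency Acoustic Backscatter Classification with the Escore Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying multifrequency echosounder backscatter into
    echo-classes with the Escore algorithm. Provides echo-integration of
    volume backscattering strength (Sv) onto elementary sampling distance
    units, dB-differencing relative to the 38 kHz reference frequency, RGB
    composite echograms, semi-supervised training of an echo-type library
    (region-of-interest selection, K-means refinement, hierarchical
    clustering into echo-classes, random-forest validation), per-class
    axis-aligned ellipsoid fitting and chi-square Escore classification of
    echo-integration cells, threshold sensitivity sweeps, theoretical
    acoustic scattering models (distorted-wave Born approximation bent
    cylinder, randomly oriented fluid bent cylinder, high-pass fluid sphere,
    resonant gas bubble, hybrid gas-plus-body) for validating echo-class
    interpretations, diel vertical migration and nautical area scattering
    coefficient metrics, and a synthetic multifrequency echogram generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    randomForest,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
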