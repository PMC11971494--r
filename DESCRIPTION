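Package: fieldcompress
Title: Basis-Function Compression for MRI Field-Probe Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating spatiotemporal magnetic-field dynamics
    (k-coefficients) from NMR field-probe phase measurements during MRI
    acquisitions. Implements real solid-harmonic probing matrices, weighted
    least-squares phase fitting with iterative concomitant-field correction,
    and data-driven compression of high-order harmonic basis functions into a
    low-rank basis learned by weighted singular value decomposition of
    multi-position calibration scans, so that high-order field perturbations
    (for example from gradient-induced eddy currents) can be characterised
    with a small probe array. Includes a synthetic-data generator for
    spiral/EPI/PGSE/OGSE/chirp gradient waveforms with linear time-invariant
    eddy-current responses, order-weighted RMSE evaluation, and singular-value
    and probe-count sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'harmonics.R'
    'fitting.R'
    'compression.R'
    'waveforms.R'
    'probes.R'
    'directions.R'
    'scenes.R'
    'evaluation.R'
    'io.R'
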