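Package: rdcsense
Title: Repetitive Direct Comparison Odor Sensing: Simulation and Signal Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the repetitive direct comparison (rDC) odor-sensing
    protocol on nanomechanical gas sensors. Provides a forward model of
    membrane-type surface stress sensor (MSS) time series -- first-order
    sorption kinetics per gas component, piezoresistive Wheatstone-bridge
    transduction, and configurable noise and drift -- under normal
    (odor/carrier) and rDC (odor/odor) alternating injection protocols, plus
    the accompanying signal-processing pipeline: analysis windowing, cycle
    segmentation, per-cycle baseline correction, cycle averaging,
    residual-RMS noise estimation, signal intensity, signal-to-noise ratio,
    and theoretical noise references for averaging and trace differencing.
    Includes a desk-scale synthetic experiment generator that reproduces the
    two-source, two-channel, six-replicate study design used to benchmark
    rDC against differencing of conventional measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
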