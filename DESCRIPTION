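Package: wavegate
Title: Simulation and Analysis of Retinal-Wave-Driven Thalamocortical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing developing thalamocortical spike and local
    field potential recordings, together with a synthetic-data generator that
    emulates neonatal retinal-wave-driven activity. Implements inter-spike-
    interval event detection and activity continuity, multi-unit spectra via
    the Fourier transform of the spike-count autocorrelation, multitaper LFP
    spectra with 1/f compensation, log-frequency resampling and band
    normalization, peri-stimulus time histogram metrics (onset latency,
    response reliability, excitation/inhibition windows, train entrainment),
    and nonparametric inference including a frequency-wise permutation test
    with max-statistic familywise correction. A delayed corticothalamic
    feedback-loop rate model and inhomogeneous Poisson wave generator allow
    every analysis stage to be exercised without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
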