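Package: laterp
Title: Lateralized ERP Analysis of Attention in Visual Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of lateralized event-related
    potentials (N2pc) recorded during visual search preceded by
    task-irrelevant symbol patterns.  Provides a synthetic-experiment
    generator with known ground-truth component parameters, epoch
    preprocessing (re-referencing, zero-phase Butterworth filtering,
    baseline correction, amplitude-threshold artifact rejection),
    contralateral-minus-ipsilateral difference waves, component measures
    (mean amplitude, signed negative area, fractional-area and
    threshold-crossing onset latencies, jackknife latency analysis with
    corrected statistics), resampling inference (signed-area permutation
    tests, cluster-mass permutation for decoding timecourses,
    bootstrapped standardized measurement error), and time-resolved
    multivariate decoding of item location with support vector machines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    signal,
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
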