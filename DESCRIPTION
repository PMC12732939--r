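Package: dbwopls
Title: Discretized Beluga Whale Optimization for NIR Wavelength Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Variable selection for near-infrared quantitative calibration.
    Couples a discretized beluga whale optimization metaheuristic (S- and
    V-shaped transfer functions, Levy-flight exploitation, whale-fall
    re-seeding) with partial least squares regression, scored by Monte
    Carlo cross-validated RMSECV. Includes the classical comparator
    selectors (uninformative variable elimination, its Monte Carlo
    variant, and a response-permutation randomization test), spectral
    preprocessing (standard normal variate, multiplicative scatter
    correction, Savitzky-Golay derivatives), Kennard-Stone sample
    partitioning, a synthetic NIR mixture generator with a known
    informative-channel mask, and a workbench that reproduces the full
    method-comparison protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
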