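Package: mgvd
Title: Multi-Sample Detection of Common Copy-Number Variation Zones in
    High-Resolution aCGH Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects common copy-number variation zones (CNVZs) and
    per-sample copy-number variants jointly across many array-CGH samples.
    Log2-ratio matrices are smoothed with a moving average, segmented at
    positions where the cross-sample signal loses consistency (Pearson
    correlation and Manhattan distance of adjacent position vectors),
    reduced to per-sample segment means, partitioned by one-dimensional
    k-means into gain/neutral/loss clusters, and scored by a weighted
    cluster-geometry function that gates candidate zones, merges and prunes
    them, and annotates aberrations of the reference sample.  Includes a
    base-pair-resolution evaluation harness (FDR, sensitivity, F1, and
    two-parameter sweeps) and a seeded simulator of multi-sample aCGH
    panels with planted variant zones.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
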