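Package: cleanv
Title: Spatial-Extent Inference for Variance Components on Cortical Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tests and localizes variance components such as test-retest
    reliability and narrow-sense heritability in vertex-level imaging data
    mapped onto triangulated surfaces. Combines spatially adjusted
    variance-component score statistics, adaptive cluster enhancement over
    geodesic neighborhoods, and permutation-based family-wise error rate
    control, together with a generative simulator for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
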