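Package: gcnparcel
Title: Individualized Cortical Parcellation with Masked Graph Convolutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individualized parcellation of the cerebral cortex from
    resting-state functional connectivity using spectral (Chebyshev) graph
    convolutions on the cortical surface mesh. Builds vertex-level brain
    graphs from triangle meshes, embeds connectivity-fingerprint signals,
    trains a two-layer graph convolutional classifier under a subject-specific
    confidence mask, and evaluates parcellations via test-retest reliability
    (Dice), topographic and connectional variability (Cohen's d), functional
    homogeneity, task-activation alignment, and Dice-kernel ridge prediction
    of behavior. Includes a synthetic-cortex cohort generator (icosphere
    meshes, contiguous atlases, boundary-warped subject parcellations,
    parcel-structured BOLD-like time series, topography-linked scores) so the
    full pipeline is testable without restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    signal,
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
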