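Package: vicnet
Title: Distance-Correlation Connectivity and Local Efficiency of Visual
    Resting-State Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for resting-state functional connectivity of
    the visual intrinsic connectivity networks (primary visual, higher
    visual and visuospatial). Computes multivariate U-centered
    distance-correlation connectivity between region-of-interest voxel
    patches, Fisher-z edge matrices, sparsity-swept weighted nodal local
    efficiency with area-under-curve summaries, and two-group statistics
    (mixed-design repeated-measures ANOVA, pooled t-tests, Storey pFDR
    q-values, acuity correlations). Includes a 19-node visual atlas, a
    temporal preprocessing stage (framewise-displacement censoring,
    polynomial detrending, band-pass filtering, motion-confound
    regression), and a seeded synthetic two-group cohort generator that
    emulates an amblyopia versus control resting-state design.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    igraph,
    RNifti,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
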