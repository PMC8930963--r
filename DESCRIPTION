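Package: motorecm
Title: Eigenvector Centrality Mapping and Behavioural Scoring for
    Longitudinal Motor Sequence Learning Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal resting-state fMRI studies of
    motor sequence learning with a motor-execution-matched control group.
    Implements behavioural scoring of continuous pinch-force tracking trials
    (cross-correlation temporal synchronization and lag-aligned root mean
    squared error), mixed repeated-measures ANOVA with sphericity
    corrections and Tukey post hocs, resting-state BOLD time-series cleaning
    (confound regression, detrending, band-pass filtering, mask-aware
    Gaussian smoothing), matrix-free voxel-wise eigenvector centrality
    mapping with a dense eigendecomposition oracle, and group-by-time
    interaction inference on centrality change maps with permutation
    cluster-level FDR correction and a formal sequence-specificity
    classification. Includes synthetic-data generators (force traces,
    behavioural cohorts, 4D BOLD phantoms with planted group-by-time
    connectivity effects) so the full pipeline is testable without access
    to raw neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
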