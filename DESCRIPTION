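Package: resit
Type: Package
Title: Equivalent-Source Interpolation of Bad EEG Channels with
    Reference Standardization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reconstructs bad scalp-EEG channels with the reference
    electrode standardization interpolation technique (RESIT): equivalent
    dipole sources on a spherical-cap-plus-plane layer are estimated from
    the good channels through a three-concentric-sphere lead field and a
    Moore-Penrose pseudoinverse, then forward-projected to every electrode,
    yielding interpolated data referenced to infinity. Includes the two
    standard baselines (neighbor averaging and spherical-spline
    interpolation), reference transforms for data and lead fields, an
    evaluation harness that injects scattered or adjacent bad channels and
    scores absolute error, relative error and Pearson correlation, and a
    forward simulator of resting-state and event-related scalp EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
biocViews: Electrophysiology, Preprocessing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
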