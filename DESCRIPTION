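Package: dynfc
Title: Task-Related Dynamics of Functional Brain Network Topology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sliding-window analysis of task-related functional connectivity
    dynamics in block-design fMRI. Extracts region-of-interest (ROI) time
    series from 4D NIfTI volumes or delimited matrices, band-limits them by
    frequency-domain or maximal-overlap discrete wavelet transform (MODWT)
    filtering, builds windowed Pearson correlation matrices (rectangular or
    Gaussian-tapered), marks task-stimulation-related windows with a temporal
    inclusive mask derived from the hemodynamic response and condition
    coverage, binarizes networks by absolute, proportional or wiring-cost
    thresholds, computes global and nodal graph-theoretical properties with
    random-network normalization, and quantifies topological stability as the
    variance of each property over masked windows, with group averaging and
    paired comparison of task-masked versus full-duration variances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml, RNifti
Suggests: testthat (>= 3.0.0), igraph, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
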