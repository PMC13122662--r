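Package: conntraj
Title: Connectivity-Based Trajectory Reconstruction for Single-Cell State Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs branching differentiation trajectories from single-cell
    RNA-seq count matrices using an ensemble connectivity approach: hashtag
    demultiplexing with fold-change doublet filtering and a Poisson doublet-rate
    estimator, distribution-based per-gene background correction, classical
    multidimensional scaling, a CLARA k-medoids clustering ensemble, per-run
    minimum-spanning-tree cluster connectivity averaged into per-cell
    connectivity scores, variance-ratio-criterion ranking of candidate
    clusterings, and lineage curves with arc-length pseudotime. Ships a
    synthetic generator of branching pluripotency-state data (primed, bridge,
    intermediate hub, naive, ectoderm, mesoderm) so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    cluster,
    stats,
    utils,
    grDevices,
    methods,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
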