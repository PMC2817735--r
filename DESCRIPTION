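Package: qtlci
Title: Positional Confidence Intervals for QTL Detected by Composite Interval Mapping
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and inference toolkit for positional confidence
    intervals of quantitative trait loci (QTL) mapped by composite interval
    mapping (CIM) in recombinant inbred line (RIL) populations. Implements a
    regression-based CIM engine (stepwise cofactor selection, flanking-marker
    conditional expectations, LOD profiles on a 1 cM grid with a blockout
    window), three positional interval procedures (LOD support intervals,
    naive bootstrap percentile intervals with frozen cofactors, and bootstrap
    percentile intervals with per-replicate cofactor re-selection), permutation
    significance thresholds, and a benchmark RIL simulator for
    coverage-probability and interval-width studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
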