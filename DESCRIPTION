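Package: rcdscan
Title: Detection and Dynamics of Replicon Cluster Domains in Early
    Replicating DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for EdU pull-down sequencing (EdU-seq) time
    courses of early S phase. Normalises binned pull-down tracks against
    genomic input controls (reads-per-million scaling, broken-line breakpoint
    isolation of background bins and ratio-mode background subtraction),
    locates Replicon Cluster Domains (RCDs) by multiscale Ricker-wavelet
    matched filtering with a late-domain percentile cutoff, quantifies
    per-domain width growth across successive EdU pulses by optimal-wavelet
    and Gaussian fitting, tracks the filling of inter-domain valleys, and
    scores the "domino" tendency of adjacent domains to activate in sequence
    via height-order permutation classes and an adjacent-height similarity
    metric. A kinetic simulator of clustered replication origins (stochastic
    per-cell activation, bidirectional fork elongation, Poisson read
    sampling) provides ground-truthed synthetic data for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
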