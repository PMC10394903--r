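Package: squidr
Title: Bulk RNA-Seq Deconvolution with Concurrent Single-Cell References
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates cell-type proportions in bulk RNA-seq samples from
    concurrent single-cell or single-nuclei RNA-seq references. Implements
    SQUID (Single-cell RNA Quantity Informed Deconvolution): a per-gene
    linear transformation of bulk profiles into single-cell measurement
    space, fitted on concurrent pseudobulk profiles, followed by dampened
    weighted least-squares deconvolution over all shared nonzero genes.
    Also provides ordinary, non-negative and robust least-squares baseline
    solvers, single-cell quality control and normalization utilities,
    cluster-profile and marker derivation, correlation-based cluster
    merging, a leave-one-out cross-validation driver, benchmarking against
    gold-standard compositions, and a synthetic concurrent-profile
    generator with known ground truth and a tunable cross-platform bias
    model.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    pracma,
    edgeR,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
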