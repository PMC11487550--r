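Package: imos
Title: Multi-Omic and Single-Cell Screening of Immune Checkpoint Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an integrated multi-omic and single-cell discovery
    cascade for nominating candidate immune-checkpoint genes in tumor
    cohorts.  Bulk expression cohorts are stratified by a rank-based
    single-sample immune enrichment score; differentially expressed genes
    between immune-high and immune-low tumors are screened genome-wide for
    overall-survival association with Kaplan-Meier/log-rank tests and
    classified as beneficial or harmful; survivors are validated across
    independent cohorts and filtered through copy-number, methylation and
    mutation evidence gates; labeled single-cell data localize each
    candidate to the cell type that expresses it.  A synthetic-cohort
    generator with planted, known-truth signal (censored survival, an
    immune-infiltration latent factor, copy-number and methylation coupling,
    multi-cell-type counts) makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    limma,
    optparse,
    yaml
Config/testthat/edition: 3
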