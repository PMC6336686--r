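Package: miRegNet
Title: Statistics for microRNA-Nuclear Receptor Regulatory Network Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative statistical procedures for linking a microRNA to a
    nuclear-receptor regulatory network and to hormone-receptor signaling in
    cancer cohorts. Provides cistrome-transcriptome bootstrap association
    tests with peak-to-TSS annotation and interval-overlap significance,
    classification of knockdown "dampening" of a hormone-responsive
    transcriptome, keyword meta-group mining over gene-set enrichment
    results, tumor-versus-normal Z-score outlier screens with hierarchical
    clustering and disease-free-survival linkage, quartile-stratified
    correlation-shift analysis, microRNA consensus target voting and
    biotin-pulldown targetome calling. A synthetic-cohort generator with
    planted effect structure (correlations per stratum, dampening factors,
    outlier subgroups, hazard ratios) makes the whole pipeline testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StatisticalMethod, GeneExpression, Transcriptomics, Survival,
    ChIPSeq, GeneRegulation
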