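Package: sensitizeR
Title: Integrated Drug-Sensitizer Discovery from Pooled shRNA Screens and
    Quantitative Proteomics
Version: 0.1.0
Authors@R:
    person("Screen", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of pooled kinome shRNA dropout (sensitizer)
    screens together with triplex isotope-label (phospho)proteomics.
    Provides amplicon demultiplexing and hairpin counting, median-of-ratios
    size-factor normalization, method-of-moments negative-binomial
    dispersion estimation with a parametric mean-dispersion trend, an exact
    conditioned negative-binomial depletion test, a two-timepoint hairpin
    filter cascade with dual-screen gene-level hit calling, one- and
    two-sample t-test differential analysis of triplex log-ratios with
    phosphosite localization filtering, hypergeometric over-representation
    analysis with Benjamini-Hochberg correction, four-parameter logistic
    dose-response fitting for ICx estimation, and an evidence-integration
    step ranking screen hits by proteomic support.  Includes synthetic-data
    generators with planted, recoverable ground truth so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
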