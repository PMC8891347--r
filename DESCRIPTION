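Package: hybridpanel
Title: SNP Panel Design and Bayesian Hybrid-Class Assignment for
    Intra-Specific Hybridization Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and deploying high-differentiation SNP
    panels that distinguish pure-stock and advanced hybrid classes (F1,
    F2, first backcrosses) between two intra-specific forms, such as
    anadromous sockeye salmon and resident kokanee. Provides a
    candidate-locus filter chain (call rate, minor allele frequency,
    homeolog heterozygosity-excess screening, Hardy-Weinberg exact tests,
    Weir-Cockerham theta ranking, tag-position windows, linkage pruning,
    primer-dropout modelling), Mendelian simulation of six
    genotype-frequency classes, Bayesian genotype-frequency-class
    assignment in deterministic plug-in and Gibbs-sampling modes,
    assignment power evaluation (accuracy, efficiency, power, Type I/II
    error), cohort stock-composition analysis, and a synthetic RAD-like
    data generator so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
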