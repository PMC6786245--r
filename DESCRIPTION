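Package: haplosweep
Title: Selection-Signature Scans from Phased SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of selection signatures in structured populations from
    phased biallelic SNP data. Implements extended haplotype homozygosity
    (EHH) profiles, the integrated haplotype score (iHS) with
    frequency-binned standardization, the cross-population XP-EHH statistic,
    and a Bayesian F_ST outlier model with a reversible-jump MCMC sampler
    over locus-specific (alpha) and population-specific (beta) effects on
    logit F_ST. Includes marker and sample quality-control filters
    (call rate, minor allele frequency, Hardy-Weinberg exact test, LD
    pruning), diversity and linkage-disequilibrium-decay summaries, PCA,
    rule-based calling of candidate selected regions, and forward
    Wright-Fisher and island-model simulators for generating phased panels
    and allele-count tables with known truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
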