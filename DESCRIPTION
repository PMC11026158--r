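Package: meiorec
Title: Meiotic Recombination Phenotypes, Crossover Interference and
    Case-Control Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing meiotic crossover data: construction of
    per-meiosis recombination phenotypes (crossover count, hotspot usage,
    telomere distance, GC content and replication timing of crossovers),
    rank-inverse-normal transformation and additive genotype-phenotype
    association with a chromosome-length interaction regression,
    maximum-likelihood fitting of the Housworth-Stahl crossover
    interference model (interference shape and escape proportion) with a
    carrier/noncarrier likelihood-ratio test, and fixed-effects
    inverse-variance meta-analysis of case-control association summary
    statistics with Cochran's Q heterogeneity and class-based weighted
    Bonferroni thresholds. Includes a fully seeded synthetic-data
    generator (gamma-renewal chiasma process with an escape pathway,
    carrier-specific parameters and length-dependent distal-shift map
    distortion; case-control cohorts with a calibrated per-allele odds
    ratio) so every stage of the pipeline can be exercised and validated
    by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    yaml
Config/testthat/edition: 3
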