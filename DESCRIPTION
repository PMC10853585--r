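Package: gsihap
Title: Genetic Stock Identification with Microhaplotype Baselines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for evaluating genetic stock identification
    (GSI) baselines built from amplicon sequencing data, motivated by
    mixed-stock monitoring of Snake River basin steelhead. Provides a
    microhaplotype-aware genotype caller for per-allele read counts
    (multinomial likelihood with a per-read error model and posterior
    thresholding), locus and individual quality control (Hardy-Weinberg
    permutation tests with Benjamini-Yekutieli FDR control, heterozygote
    allele-balance paralog diagnostics, genotyping-rate and duplicate
    filters), per-locus multi-allelic Weir-Cockerham F_ST, leave-one-out
    self-assignment with Dirichlet-smoothed conditional genotype
    likelihoods, Bayesian mixture-proportion inference by Gibbs sampling,
    simulated-mixture bias assessment, PIT-tag concordance scoring, and
    chi-square / rank-based comparisons between baseline and marker-panel
    configurations. A hierarchical Balding-Nichols synthetic-data generator
    emulates the reporting-unit / population structure of a real steelhead
    baseline so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
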