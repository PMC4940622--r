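Package: allylgwa
Title: Glucosinolate Trait Algebra and Ridge-Regression GWA for Allyl
    Feeding Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing exogenous allyl-glucosinolate feeding
    experiments across Arabidopsis thaliana accession panels: construction
    of derived glucosinolate traits (summations and oxidation ratios),
    treatment-response statistics, accession-by-treatment ANOVA,
    least-square means, broad-sense heritability from expected mean
    squares, genome-wide association by SNP-BLUP ridge regression with a
    heteroscedastic-effects (HEM) second pass and permutation-derived
    significance thresholds, gene-level candidate calling, condition
    overlap analysis, and expression-based candidate prioritisation. A
    synthetic-cohort generator emulates the design of such studies
    (inbred genotype panels, replicated two-treatment phenotyping,
    compound profiles with an AOP2 presence/absence split) so the full
    pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
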