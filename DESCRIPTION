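Package: invadeR
Title: Invasion-History Inference from ddRADseq SNPs with ABC Random Forests
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the introduction history of invasive plant
    populations from reduced-representation (ddRADseq) SNP data. Provides a
    post-calling SNP filter cascade (sample missingness, genotype depth
    masking, biallelic/missingness/MAF site filters, one-SNP-per-RAD-locus
    thinning), population diversity and differentiation statistics
    (heterozygosity, private alleles, Weir-Cockerham FST, AMOVA Phi-ST,
    standardized FST, Nei's D, f3 admixture statistics), a coalescent SNP
    simulator for user-defined demographic scenarios with ghost populations,
    founder bottlenecks and admixture, approximate Bayesian computation with
    random forests for scenario choice (including a sequential tournament of
    scenario subsets), regression-adjusted parameter estimation with logit
    transforms, posterior-predictive model checking, allele-balance ploidy
    inference by fixed-versus-free Gaussian mixture likelihoods, and
    flow-cytometry 2C DNA content and genome-size estimation against an
    internal reference standard.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    ranger,
    MASS,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
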