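Package: breedscan
Title: Across-Breed GWAS with Breed Prevalence Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for categorical genome-wide association on cohorts where
    the phenotype is a breed-level disease prevalence rather than an
    individual measurement. Implements two-stage variant and sample quality
    control with a detailed filtering ledger, breed-assignment verification
    by bootstrapped identity-by-state distances, neighbor-joining trees and
    majority-rule consensus, a centered genomic relatedness matrix with
    scree-based eigenvector selection, and four association engines: a
    restricted-maximum-likelihood linear mixed model with Wald tests, a
    binary case-control mixed model over prevalence-dichotomised breeds, a
    sliding-window haplotype scan with EM haplotype frequency estimation,
    and a weighted least squares scan on breed-averaged allele dosages
    weighted by breed sample proportions. Includes multiple-testing
    thresholds, genomic-inflation diagnostics, region collapsing, gene
    annotation, and a Balding-Nichols multi-breed cohort simulator with
    planted large-effect variants for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    ape,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
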