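Package: rohmap
Title: Runs of Homozygosity Detection, Inbreeding Statistics and
    Homozygosity Mapping for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in genotype data with the
    sliding-window observational genotype-counting algorithm, computes
    per-individual homozygosity parameters (NROH, SROH, AVROH and the
    genomic inbreeding coefficient F_ROH), derives consensus ROHs shared
    across individuals with allelic matching, tests ROH burden and
    per-region association with a binary phenotype under logistic models,
    classifies inbred individuals, builds homozygosity maps from inbred
    cases to prioritize candidate recessive regions, and filters
    sequencing variants inside individual ROHs.  Includes a pedigree
    gene-dropping simulator of realized inbreeding coefficients and a
    synthetic-cohort generator with implanted autozygous tracts for
    validation without access to restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    IRanges,
    vcfR,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
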