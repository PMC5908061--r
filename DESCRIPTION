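Package: sweepreg
Title: Selective-Sweep and Regulatory-Acceleration Scans for Candidate
    Cis-Regulatory Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects signatures of positive selection on candidate
    cis-regulatory regions from phased population haplotypes and primate
    multiple alignments. Implements windowed nucleotide diversity and
    Tajima's D scans, extended haplotype homozygosity (EHH) and the
    standardized integrated haplotype score (iHS) with selected-allele
    inference, a composite likelihood ratio (CLR) sweep scan with an
    LD-based omega statistic and a simulation-calibrated compound outlier
    test, a phyloP-style subtree likelihood-ratio test for lineage-specific
    acceleration, position weight matrix scanning with exact p-values and
    allele binding-affinity effects, and a multi-filter enhancer-promoter
    candidate funnel. Ships seeded coalescent, Wright-Fisher and
    phylogenetic simulators that generate every input the pipeline needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
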