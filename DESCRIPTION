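Package: ascbias
Title: Assessing and Mitigating SNP Ascertainment Bias in Diversity Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how SNP-array ascertainment distorts population-genetic
    diversity statistics relative to a whole-genome reference, and how well
    common filtering strategies mitigate the distortion. Given individually
    genotyped array data and pooled-sequencing allele frequencies over the same
    populations, the package harmonizes the two sources, applies call-rate,
    minor-allele-frequency, wild-population-polymorphism and linkage-
    disequilibrium pruning filters (alone and in combination), and compares
    allele-frequency spectra, expected heterozygosity, pairwise fixation
    indices, Nei standard genetic distances, neighbor-joining trees and
    principal components between the filtered array versions and replicate
    subsets of the reference. A Balding-Nichols based generator simulates
    structured populations, linkage-disequilibrium blocks, pooled read
    sampling and discovery-panel SNP ascertainment so the whole pipeline is
    testable on synthetic data.
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
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
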