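Package: introScan
Title: Block-Based Detection of Genetic Introgression in Structured
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-genome detection and mapping of genetic introgression
    between subpopulations of a structured species (motivated by Asian
    cultivated rice), from diploid SNP genotypes. Implements two
    complementary block-wise detectors: a phylogenetic-tree method
    (allele-sharing distances, neighbor-joining trees and a
    nearest-leaf classification rule per 500 kb block, with a
    permutation null for genome-wide significant-region calling) and a
    windowed ABBA-BABA D-statistic scan with block-jackknife Z scores.
    Adds per-block nucleotide diversity and Hudson Fst tracks,
    supervised two-panel local-ancestry estimation with admixture
    association mapping against quantitative phenotypes, a
    Balding-Nichols population simulator with planted introgression
    tracts for ground-truth benchmarking, and a reproducible pipeline
    driver with cross-method comparison output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
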