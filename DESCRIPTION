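Package: slafpop
Title: SLAF-Seq Design and Population Genomics for Amphidiploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing reduced-representation
    (SLAF-seq) genotyping studies in amphidiploid species such as Brassica
    napus. Provides in-silico double digestion and enzyme-scheme scoring,
    genotype-panel filtering by minor allele frequency and call rate,
    SNP hotspot and SNP-rich-region statistics in sliding windows,
    marker-based kinship, p-distance and neighbour-joining trees, PCA,
    admixture-model ancestry estimation with cross-validated choice of K,
    pairwise r2 linkage disequilibrium with decay-distance estimation, and
    Gabriel-style D-prime confidence-interval haplotype blocks with
    per-subgenome summaries. A seeded synthetic-data generator produces
    genomes, structured genotype panels and reads with the statistical
    structure these analyses assume, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    methods,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    phangorn
Config/testthat/edition: 3
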