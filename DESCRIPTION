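Package: phagepan
Title: Comparative Genomics of Dairy Phage Populations and Their Host
    Polysaccharide Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale comparative-genomics pipeline for dairy
    Streptococcus thermophilus phages and their host strains. Builds a
    pangenome by bidirectional-best-hit orthology over exact pairwise
    protein alignments, groups phages by gene content (Jaccard distance,
    UPGMA), extracts per-group core genomes and receptor-binding-protein
    (RBP) phylogenies by distance-based neighbor joining with bootstrap
    support, types host strains by the gene content of their eps and rgp
    polysaccharide operons located between flanking marker genes, and
    quantifies the association between RBP lineage and host genotype with
    exact sampling-without-replacement (hypergeometric) probabilities. A
    population simulator with planted ground truth makes every stage
    testable without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
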