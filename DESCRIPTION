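Package: crisprase
Title: Allele-Specific Analysis of CRISPR Enhancer-Deletion Experiments in
    Hybrid Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse double-CRISPR enhancer-deletion experiments in
    F1 hybrid (CAST x 129) embryonic stem cells, together with a fully
    synthetic experiment generator with known ground truth. Implements
    variant-level mapping-bias, copy-number-balance and heterozygosity QC of
    phased SNPs/indels; SNP-level assignment of strand-specific RNA-seq reads
    to parental alleles with per-gene allele-specific counts and pseudo-count
    log-ratio allele-specificity; FPKM computation and fold-change signature
    calling with binomial enrichment and overlap tests; deletion-clone
    genotyping from junction PCR, delta-delta-Ct copy number and
    junction-SNP sequencing, including the allelic deletion-frequency
    statistic; and restriction-fragment anchor contact profiles with a
    distance-decay expected model and Poisson loop calling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    IRanges,
    S4Vectors,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
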