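Package: lakestream
Title: Permutation Inference, F-Statistics and Haplotype Networks for
    Lake-Stream Stickleback Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for repeated lake-stream life-history
    divergence in threespine stickleback: permutation tests with bespoke
    statistics (group mean differences, variance of population means,
    chi-square, one-way ANOVA F), landmark-based centroid size,
    multi-allelic Weir-Cockerham F_ST with permutation P-values and
    Hedrick-standardized F'_ST via maximum-differentiation allele
    recoding, and mitochondrial D-loop haplotype collapsing with
    minimum-spanning networks. Includes readers and writers for phenotype
    TSV, TPS landmark, GENEPOP genotype and FASTA alignment files, and a
    synthetic-data module emulating habitat-structured phenotypes,
    island-model microsatellite genotypes and haplotype alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
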