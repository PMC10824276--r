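Package: otterpg
Title: Population-Genomic Diversity, Inbreeding and Mutation-Load Analysis for Small Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for conservation-genomic analysis of
    multi-sample SNP data from small, fragmented populations. Reads and
    filters multi-sample VCFs (per-genotype depth and quality thresholds,
    biallelic-SNP and missingness rules), computes per-individual
    heterozygosity, within-population nucleotide diversity and the
    between-population divergence statistics d_xy and d_a, builds site
    frequency spectra with hypergeometric projection, thins SNPs by
    windowed linkage-disequilibrium pruning with Hardy-Weinberg and
    minor-allele-frequency filters ahead of principal component analysis,
    detects runs of homozygosity with a windowed scanning algorithm and
    derives the genomic inbreeding coefficient F_ROH, annotates coding
    variants against a reference genome and GFF3 gene models, polarizes
    alleles with an outgroup genome and scores amino-acid substitutions
    with the Grantham physicochemical distance to summarize per-genome
    mutation load, and compares groups with one-way ANOVA and the
    Tukey-Kramer HSD test. Ships a synthetic-cohort generator that plants
    known allele frequencies, autozygous tracts and coding-variant
    consequences so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
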