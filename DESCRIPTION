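Package: epipotential
Title: Epigenetic Potential from CpG Gain and Loss Variants in Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-individual epigenetic potential from a multi-sample
    VCF and a reference genome by classifying biallelic SNPs as CpG-loss or
    CpG-gain ("polyCpG") polymorphisms, counting the CpG-forming alleles each
    individual carries, annotating variant and background CpG positions into
    promoter/exon/intron/intergenic categories, testing category enrichment
    against the genomic CpG background with exact binomial tests, and comparing
    dispersal-defined groups with missingness-weighted (mixed) linear models.
    Includes a seeded synthetic-cohort generator (reference FASTA, BED12 gene
    models, VCF, metadata) with full ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    car,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
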