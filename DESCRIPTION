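Package: meqtlscan
Title: Methylation Quantitative Trait Locus Discovery from Array SNP Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering methylation quantitative
    trait loci (meQTLs) from Illumina methylation arrays. Calls biallelic
    genotypes from the three-peaked signal of the array's SNP control probes,
    applies minor-allele-frequency, missingness and Hardy-Weinberg quality
    filters, scans every SNP-CpG pair with an age-adjusted linear regression
    of the methylation beta value on minor-allele dosage, screens discoveries
    with a per-SNP Benjamini-Hochberg false discovery rate, classifies
    significant pairs as cis, long-distance cis or trans from genomic
    coordinates, and compares case- and control-stratified scans to label
    group-specific regulatory relationships. A synthetic-data generator with
    planted effects makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
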