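Package: heveacore
Title: SNP Diversity, Population Structure and Core Collection Construction
    for Germplasm Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for SNP-based germplasm
    characterisation of plant collections such as cold-resistant rubber
    tree (Hevea brasiliensis) accessions. Reads multi-sample VCFs into a
    coded genotype panel (0/1/2 dosage, 9 missing), applies sample,
    variant and marker-panel filters, computes per-locus diversity
    statistics (expected heterozygosity, polymorphism information
    content, site nucleotide diversity), infers population structure via
    an EM admixture model with Evanno delta-K model selection,
    neighbor-joining clustering and variance-standardised PCA, builds
    cluster-stratified core collections by stepwise redundancy
    elimination with diversity-retention evaluation across sampling
    ratios, and derives per-accession SNP fingerprint digit codes with
    QR payloads. Includes a Balding-Nichols genotype simulator with
    ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    mclust,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
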