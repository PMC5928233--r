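Package: paralogsift
Title: Paralog-Aware SNP Filtering and Characterization for Genomes with
    Residual Tetraploidy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control and characterization pipeline for SNP discovery
    in partially tetraploid genomes such as salmonids. Implements a five-stage
    variant filter cascade (quality/bi-allelic/indel proximity, low-complexity
    masking, maximum depth, minimum genotyped samples), a doubled-haploid
    heterozygosity screen that flags paralogous sequence variants (PSVs) and
    multisite variants (MSVs), two-caller concordance classification, and
    population statistics (minor allele frequency spectra, per-population
    polymorphism, windowed nucleotide diversity, per-chromosome SNP density).
    Includes a lightweight sequence-ontology effect annotator and a synthetic
    data generator that emulates a resequencing study design with duplicated
    chromosome arms, doubled-haploid lines, and two discordant variant
    callers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    broom,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
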