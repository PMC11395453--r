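Package: ovipop
Title: Population Genomics of Ovine SNP-Array Data: Diversity, ROH,
    Selection Signatures and Repeatability-Model GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for medium-density SNP-array population
    genomics in livestock, built around the analyses used to dissect
    prolificacy in Hu sheep. Provides genotype input/output for PLINK
    (ped/map, bed/bim/fam) and VCF with call-rate, minor-allele-frequency
    and exact Hardy-Weinberg quality control; per-marker and windowed
    genetic diversity statistics, linkage-disequilibrium decay and
    LD-based historical effective population size; sliding-window runs of
    homozygosity (ROH) with a false-positive-controlled minimum run
    length; eight genomic inbreeding coefficients (F_ROH by length class,
    F_HOM, F_GRM, F_UNI) and their correlation structure; three
    complementary selection-signature scans (ROH islands, a composite
    likelihood ratio sweep test, and iHS from extended haplotype
    homozygosity) with a two-method consensus caller; a mixed-model GWAS
    for repeated records under an animal repeatability model with REML
    variance components and FDR control; and interval-based candidate
    gene annotation. A forward Wright-Fisher simulator with plantable
    autozygosity, sweeps and QTL effects supplies ground-truth panels for
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
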