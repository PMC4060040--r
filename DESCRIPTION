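Package: snapvar
Title: In-Memory Germline and Somatic Variant Calling with a 16-Genotype
    SNP+Indel Model and an Indexed Pileup Snapshot Store
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully in-memory secondary-analysis pipeline for
    short-read sequencing data: seed-and-extend paired-end alignment with
    banded affine-gap dynamic programming, duplicate marking without
    external sorting, base quality score recalibration, exhaustive
    realignment of reads against hypothetical indel haplotypes, and joint
    Bayesian genotyping over a 16-genotype diploid space in which SNP and
    indel alleles compete at every site. Per-base evidence is persisted in a
    block-compressed, indexed snapshot store that supports repeatable
    variant calling and region queries without reprocessing reads. Includes
    a tumor-normal somatic SNV/indel caller and a depth-ratio CNV segmenter
    operating directly on snapshot files, a random-forest call filter, a
    Mendelian trio conflict counter, an Illumina-style diploid read
    simulator with truth tracking, and a truth-versus-called evaluation
    layer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    data.table,
    randomForest,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    Rsamtools,
    rtracklayer,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
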