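Package: ConsensusVariants
Title: Multi-Caller Consensus Variant Prioritization for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Variant prioritization for tumor/benign sequencing cohorts built
    around a strict multi-caller consensus: per-caller VCFs are normalized
    (allele trimming and left-alignment), quality-filtered (depth, genotype
    quality, heterozygote allelic balance, FILTER status) and intersected on
    exact (contig, position, ref, alt) keys across callers. Downstream stages
    match consensus variants against clinical annotation tables, bin
    population-frequency rarity, rank occurrence across samples, test the
    zygosity-by-Gleason-grade pattern, intersect copy-number variants with
    population structural-variant tables under a Wilson-bound rarity filter,
    and profile androgen-receptor CAG-repeat length mosaicism from
    flank-anchored reads. A fully parameterized synthetic-cohort generator
    (truth variants, per-caller VCFs with controlled noise, annotation and
    frequency tables, repeat-locus reads) makes every stage testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
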