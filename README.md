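# ConsensusVariants

Variant prioritization for prostate-cancer (and similar tumor/benign)
sequencing cohorts built around a **strict multi-caller consensus**: a
variant is trusted only when several independent callers report the
identical normalized `(contig, position, ref, alt)` key for a sample.
Around that core the package implements the full desk-side analysis a
cohort study needs, plus a deterministic synthetic-cohort generator so
every stage is testable without access to patient sequence data.

## Who this is for

Bioinformaticians analyzing multi-caller VCF call sets from tumor and
benign-comparator tissue (e.g. malignant prostate adenocarcinoma vs benign
prostatic hyperplasia, BPH), who need reproducible consensus extraction,
clinical annotation matching, population-frequency rarity filtering, and
cohort-level stratification — and a way to validate the whole pipeline
against planted ground truth.

## What it computes

1. **Consensus extraction** (`extractConsensus`): per-caller VCFs are split
   to biallelic records, normalized to the unique minimal left-aligned
   representation, quality-filtered (DP ≥ 20, GQ ≥ 20, heterozygote allelic
   balance AB = AD_alt/(AD_ref+AD_alt) ≥ 0.2, FILTER == PASS; all boundaries
   inclusive, all thresholds configurable), then intersected on exact keys
   across callers (default: all four; `required_callers = 3` supports
   low-pass designs).
2. **Annotation matching** (`matchVariants`, `filterByClassification`,
   `partitionSomaticGermline`): exact position + alternate-allele joins
   against ClinVar/COSMIC-like tables, a closed classification vocabulary
   {Pathogenic, Likely-pathogenic, Likely-benign, Benign, VUS, Conflicting},
   and the cohort somatic rule — somatic annotation *and* no BPH carrier.
3. **Rarity binning** (`classifyRarity`, `rarityReport`): gnomAD-style MAF
   bins with the inclusive extremely-rare boundary MAF ≤ 0.001 and the
   conventional common cutoff MAF ≥ 0.05; GenomeIndia-style AAF carried for
   context; strict four-field GWAS-catalog matching (`matchGwas`).
4. **Cohort stratification** (`rankOccurrence`,
   `zygosityGradeAssociation`): shared-vs-unique occurrence ranking and the
   per-variant 2×2 zygosity (hom/het) by Gleason grade (4+4, 4+3 = high)
   exact conditional test.
5. **CNV overlap** (`intersectSvs`, `bonaFideFilter`, `snvInCnv`): interval
   intersection against population SV tables; a cohort CNV is *bona fide*
   when the 90% Wilson confidence upper bound of its best-overlapping
   population SV's allele frequency is below 0.02.
6. **CAG-repeat mosaicism** (`countRepeatUnits`, `buildRepeatProfile`,
   `cohortMosaicismSummary`): exact flank-anchored repeat counting in reads
   spanning the androgen-receptor CAG locus; an allele is supported at ≥ 3
   reads and ≥ 20% of spanning reads; mosaicism = ≥ 2 supported alleles;
   a supported allele of ≤ 18 repeats is the high-risk class.
7. **Synthetic cohorts** (`simulateTruth`, `emitCallerVcfs`,
   `emitAnnotationTables`, `simulateRepeatReads`): seeded generators for
   truth variants (49 samples, 30 malignant / 5 BPH by default, somatic
   variants homozygous in high-Gleason carriers and heterozygous otherwise),
   per-caller VCFs with configurable false-negative/false-positive rates and
   representation dialects, annotation/frequency/SV tables with decoys, and
   repeat-locus reads with planted allele mixtures.

## Worked example

```r
library(ConsensusVariants)

# 1. The packaged 12-variant worked example
fx <- fixtureAnnotationRecords()
fr <- fixtureFrequencyTables()
variants <- joinFrequencies(fx, fr$gnomad, fr$gip)
variants$rarity <- classifyRarity(variants$gnomad_maf)
report <- rarityReport(variants, variants$classification)
str(report[c("total", "extremely_rare", "common", "gnomad_not_reported")])
#> List of 4
#>  $ total              : int 12
#>  $ extremely_rare     : int 4
#>  $ common             : int 1
#>  $ gnomad_not_reported: int 7
subset(variants, rarity == "common",
       c(rsid, gene, ref, alt, gnomad_maf, gip_aaf))
#>        rsid gene ref alt gnomad_maf  gip_aaf
#> 9 rs1042522 TP53   G   C       0.38 0.521759
```

Of the 12 packaged consensus somatic variants, 11 are non-benign, four are
extremely rare (MAF ≤ 0.001), seven are absent from the gnomAD-like table,
and the single common variant is the TP53 polymorphism at 38% MAF.

```r
# 2. Synthetic cohort -> four-caller consensus
cohort <- simulateTruth(cohortConfig(n_samples = 10, n_malignant = 6,
                                     n_bph = 2, n_germline_truth = 60,
                                     n_somatic_truth = 6, seed = 1))
dir <- tempfile()
manifest <- emitCallerVcfs(cohort, noiseFreeProfiles(), dir)
res <- extractConsensus(manifest, cohortReference(cohort))
res$funnel
#>                stage      type n_in n_out                     reasons
#> 1          load_vcfs transform 1644  1644
#> 2 split_multiallelic transform 1644  1644
#> 3          normalize transform 1644  1644
#> 4     quality_filter    filter 1644  1644
#> 5          consensus    filter 1644   411 below_required_callers=1233
identical(sort(paste(res$consensus$key, res$consensus$sample)),
          sort(paste(truthGenotypes(cohort)$key,
                     truthGenotypes(cohort)$sample_id)))
#> [1] TRUE
```

With noise-free callers the 4-of-4 consensus recovers the planted truth
exactly (1644 per-caller records = 4 callers × 411 carrier records).

```r
# 3. CAG repeat mosaicism
reads <- simulateRepeatReads(c(16, 24), c(0.55, 0.45), n_reads = 60,
                             seed = 2)
profile <- buildRepeatProfile(countRepeatUnits(reads, sample = "S01"))
profile
#> RepeatProfile S01: 60 spanning / 0 non-spanning reads | 16:31 24:29 |
#>   alleles {16,24} | mosaic=TRUE | risk=high
```

Two supported allele lengths in one sample flag somatic mosaicism; the
16-repeat allele (≤ 18) makes the sample high risk.

A command-line front end over the same functions ships at
`inst/scripts/consensus-pipeline.R` (`simulate`, `consensus`, `all`,
`repeats`, `report` subcommands).

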