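---
title: "Consensus variant prioritization in tumor/benign cohorts: methods and design"
author: "ConsensusVariants"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Consensus variant prioritization: methods and design}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Calling variants from archival tumor tissue (FFPE blocks especially) is
noisy: fixation artifacts, uneven coverage and caller-specific biases
produce call sets that disagree substantially between tools. The strategy
implemented here trades sensitivity for precision by trusting only the
**strict cross-caller consensus**: a candidate variant is retained for a
sample only when every required caller reports the *identical* normalized
`(contig, position, ref, alt)` key. Representation differences between
callers (right-shifted indels, merged multiallelic records, un-trimmed
alleles) would defeat a naive coordinate intersection, so normalization is
the load-bearing step: every record is reduced to its unique minimal
left-aligned form before any matching.

Downstream of the consensus, the pipeline asks the questions a cohort study
asks of its variants: Which are clinically classified, and how? Which are
rare in population references? Which are shared across samples versus
private? Do pathogenic somatic variants show the expected zygosity pattern
across tumor grades? Do cohort copy-number variants coincide with known
population structural variants, and are any of those demonstrably rare? And
separately from SNVs/indels: does the androgen-receptor CAG repeat show
several distinct lengths inside one sample (somatic mosaicism), and is a
short allele (≤ 18 units, a reported risk factor for aggressive prostate
cancer) present?

# Normalization

`normalizeVariants` implements the classic trim/left-align loop: shared
trailing bases are stripped, prepending the preceding reference base
whenever an allele would otherwise become empty (this walks indels leftwards
through repeat tracts), then shared leading bases are stripped while both
alleles are longer than one base, so indels keep the mandatory single anchor
base. The result is:

* **idempotent** — normalizing a normalized record is the identity;
* **representation-invariant** — every equivalent encoding of a variant
  (any shift inside a repeat tract, any amount of shared padding) maps to
  the same key.

Both properties are tested against an independent brute-force enumerator
that lists all VCF-valid representations reproducing the same edited
haplotype and picks the minimal one (smallest total allele length, then
smallest position). Degenerate inputs are errors, not silent fixes: a ref
allele that disagrees with the reference sequence, `ref == alt`, and
left-alignment walking off position 1 all raise informative errors.

# Quality filtering

Defaults follow the whole-exome regime: `min_dp = 20`, `min_gq = 20`,
`min_het_ab = 0.2`, `require_pass = TRUE`, every boundary inclusive
(DP = 20 passes, AB = 0.2 passes). Design choices where conventions differ
between tools:

* **AB definition.** AB = `AD_alt / (AD_ref + AD_alt)` from the AD field,
  not `AD_alt / DP`: DP may include reads filtered from genotyping or
  assigned to other alternate alleles, which would deflate the balance of a
  clean het. AB is applied to heterozygotes only; a homozygous call has no
  balance expectation.
* **Missing FORMAT fields.** Strict by default: a record missing DP, GQ or
  (for a het) AD fails with reason `missing_field`. Some sparse low-pass
  caller dialects omit fields routinely, so `strict_missing = FALSE`
  treats a missing criterion as satisfied. Explicit is safer than guessing
  per-caller semantics.
* **Multiallelic decomposition.** One biallelic record per alternate
  allele; AD decomposes positionally keeping the original reference depth
  un-rescaled (the simplest defensible reading — rescaling schemes invent
  information). Genotypes are recoded against the retained allele; a het
  whose partner allele is a *different* alternate is flagged `cross_alt`.
* **All failure reasons are recorded**, not only the first, so the funnel
  report can attribute every dropped record.
* **Filter order.** Per-caller filtering happens before intersection
  (matching the sequential narrative of consensus pipelines);
  `filter_after_consensus = TRUE` inverts the order for sensitivity
  analysis.

# Consensus

Presence means a carrier genotype (het or hom-alt) for the exact key.
`required_callers` defaults to "all callers present in the input" — four in
the whole-exome design; three supports the low-pass regime where one caller
is unreliable at shallow depth. The consensus genotype is the majority vote
across supporting callers; an exact tie keeps the key but flags
`discordant_gt` with genotype `NA`, and discordant variants are excluded
from zygosity stratification (there is no principled way to pick a side).
Lowering `required_callers` can only grow the output (monotonicity,
property-tested), and at `required = all` the consensus is a subset of every
caller's filtered set.

# Annotation, partition and rarity

Joins use position + alternate allele with a reference-consistency check;
rsIDs are never join keys (they drift across builds and databases).
Classification strings map through a closed synonym vocabulary
("Variant of Uncertain Significance" = "VUS", "Conflicting pathogenicity" =
"Conflicting", etc.); duplicate keys with conflicting classifications
collapse to `Conflicting`.

The somatic/germline partition applies the cohort rule: **somatic** needs
somatic-supporting annotation origin *and* an empty intersection of the
carrier set with BPH samples. A somatic-only annotation contradicted by a
BPH carrier is demoted to *unresolved* rather than silently re-labelled
germline — the two evidence sources disagree and the pipeline says so.
Origin `both`/`unknown` with a BPH carrier goes germline. The partition is
exhaustive and disjoint by construction.

Rarity bins on the gnomAD-style MAF only: `extremely_rare` at MAF ≤ 0.001
(inclusive, the study rule), `common` at MAF ≥ 0.05 — the conventional
common-variant cutoff, chosen because the data clearly label a 38% MAF
variant common but name no boundary; it is a configurable parameter. The
GenomeIndia-style AAF column is reported for context and never drives
binning (it is an alternative-allele frequency, not necessarily a MAF).
GWAS matching is strict on all four key fields with no allele flipping:
a swapped ref/alt is not a hit.

# Stratification

High grade means Gleason patterns 4+4 and 4+3 exactly; 3+4 goes to "lower"
(only those two patterns are tied to the homozygosity observation this
reproduces). The zygosity-by-grade association uses the two-sided exact
conditional (hypergeometric) test on the per-variant 2×2 table — at
single-variant carrier counts an asymptotic test would be indefensible. The
implementation is `stats::fisher.test`; the test suite verifies its
p-values against a full margin-fixed enumeration for every 2×2 table with
n ≤ 30. Concordance is the strict pattern: *all* high-grade carriers
homozygous and *all* lower-grade/BPH carriers heterozygous. Occurrence
ranking sorts by descending carrier count with ties broken by
(contig, position, alt); "shared" means ≥ 2 carriers.

# CNV overlap and the bona fide filter

SV tables are BED-convention 0-based half-open; all conversions are
internal. Intersection reports any overlap ≥ 1 bp by default (the intersect
tool's default), with reciprocal-fraction and sv-type matching as opt-in
constraints. The bona fide rule interprets "rare at 90% confidence" as: the
upper bound of the 90% score-based (Wilson) confidence interval of the
population allele frequency of the *best-overlapping* population SV must lie
below 0.02. The Wilson bound is closed-form, behaves sensibly at zero
counts, and reduces to the point rule when allele counts are absent; SVs
with no frequency information at all are excluded (reason `no_frequency`) —
rarity cannot be demonstrated, so it is not assumed. Tightening the
threshold can only shrink the set (tested). For SNV-in-CNV co-localization
the variant position is compared directly in interval space with the
half-open convention (`start <= position < end`): a variant at the exclusive
end coordinate is outside.

# Repeat mosaicism

No standard method is assumed for measuring CAG length from reads, so the
package defines an exact, deterministic one: a read is *spanning* when it
contains an exact left-flank match followed downstream by an exact
right-flank match with a pure whole number of repeat units in between.
Interrupted tracts, missing flanks and partial units are non-spanning with
reason codes — conservative and testable, at the cost of discarding reads a
probabilistic model might rescue. Support thresholds (≥ 3 reads and ≥ 20%
of spanning reads per allele, ≥ 10 spanning reads per sample to call at
all) suppress single-read stutter artifacts; all are configurable via
`mosaicismParams`. Mosaicism is ≥ 2 supported alleles. Risk is the
any-supported-allele rule at ≤ 18 repeats inclusive — risk is tied to the
presence of a short allele, not an average. Because the denominator
convention for a cohort mosaicism rate is genuinely ambiguous, the summary
reports the fraction among callable samples *and* among all samples.

# The synthetic cohort generator

The generator fixes the study conditions: 49 samples, 30 labeled malignant
and 5 BPH (the remainder are unlabeled fresh-frozen blocks treated as
malignant by default, exposed as `unlabeled_policy`); germline truth
variants shared by k samples with k drawn from a sharing distribution
(uniform on 2..49 by default — the data constrain the range, not the
shape); somatic truth variants carried by 2-6 malignant samples, homozygous
in carriers with Gleason patterns 4+4/4+3 and heterozygous otherwise; depth
negative-binomial with mean 110 (the exome regime; a low-pass preset would
use mean ~3); GQ normal truncated to [0, 99]; het allele fractions uniform
in 0.3-0.7 and hom in 0.92-1. Caller noise — per-caller false-negative
probability, Poisson false-positive count, representation dialect
(minimal / right-shifted / multiallelic-merged), non-PASS fraction — is a
free parameter set: real per-caller error behavior is not identifiable from
published counts, so the defaults are plausible, distinct per caller, and
exercised by tests rather than asserted as estimates.

Everything is a deterministic function of the configured seed (verified
byte-identical in tests). Truth variant sites sit on a 25 bp grid so
normalized keys cannot collide even after left-alignment shifts.

What the generator deliberately does **not** emulate: read-level exome
capture and alignment, FFPE deamination artifact spectra (only a uniform
false-positive knob), caller-correlated errors (false calls are independent
across callers, which makes consensus *more* effective than reality —
passing tests bound the machinery's correctness, not real-world
sensitivity), PCR stutter in the repeat caller (the simulator can inject
±1-unit noise to stress thresholds, but the caller has no stutter model),
and linkage/population structure in germline sharing.

# Problem sizes and numerical choices

The acceptance-scale checks run on a 49-sample, four-caller cohort with
1012 truth variants (~26,000 carrier records, 196 VCFs), 500 random tract
indels for the normalization oracle, 50 random interval instances of up to
200 intervals per side, all 46,371 2×2 tables with n ≤ 30 for the exact
test, and a 200-sample repeat cohort with 36% planted mosaicism — sizes
chosen so the full suite completes in a few minutes on one CPU while still
exercising every code path at cohort scale. Exact-test agreement is
asserted at 10⁻⁹ absolute; Wilson bounds at 10⁻⁸ against a root-finder;
everything discrete (counts, keys, recovered alleles) is asserted exactly.
Binomial-bound assertions (non-PASS fraction, mixture recovery, mosaic
fraction) use fixed seeds, so they are deterministic in the suite.

# Known limitations

* The consensus treats callers symmetrically; there is no caller weighting
  or quality-aware arbitration.
* No local realignment or phasing: two callers describing one mutation as
  different haplotype edits that are not representation-equivalent will not
  intersect.
* LoH calling is out of scope (no tumor-normal pairs); the somatic call is
  annotation-origin + cohort-presence only.
* The repeat caller requires exact flank matches; heavily degraded reads
  reduce callable samples rather than degrading calls.
* Cohort SVs arrive as intervals; no CNV calling from read depth.
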