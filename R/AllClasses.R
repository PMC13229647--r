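#' @import methods
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Quality thresholds for per-caller variant filtering
#'
#' Container for the per-record quality gates applied to every caller's calls
#' before cross-caller intersection: minimum read depth (DP), minimum
#' genotype quality (GQ), minimum allelic balance for heterozygotes
#' (AB = alt depth / (ref depth + alt depth)), and whether the VCF FILTER
#' column must be \code{PASS}. All boundaries are inclusive.
#'
#' @slot min_dp numeric(1). Minimum DP; default 20.
#' @slot min_gq numeric(1). Minimum GQ; default 20.
#' @slot min_het_ab numeric(1). Minimum AB for heterozygous calls, in
#'   \[0, 0.5\]; default 0.2. Homozygous calls are not AB-filtered.
#' @slot require_pass logical(1). Require FILTER == "PASS"; default TRUE.
#' @slot strict_missing logical(1). If TRUE (default) a record missing DP, GQ
#'   or (for a het) AD fails with reason \code{missing_field}; if FALSE the
#'   missing criterion is treated as satisfied (useful for sparse low-pass
#'   caller dialects).
#'
#' @examples
#' qualityThresholds()
#' qualityThresholds(min_dp = 10, strict_missing = FALSE)
#' @export
setClass("QualityThresholds",
  representation(min_dp = "numeric", min_gq = "numeric",
                 min_het_ab = "numeric", require_pass = "logical",
                 strict_missing = "logical"))

setValidity("QualityThresholds", function(object) {
  msg <- character()
  if (length(object@min_dp) != 1L || object@min_dp < 0)
    msg <- c(msg, "min_dp must be a single non-negative number")
  if (length(object@min_gq) != 1L || object@min_gq < 0)
    msg <- c(msg, "min_gq must be a single non-negative number")
  if (length(object@min_het_ab) != 1L ||
      object@min_het_ab < 0 || object@min_het_ab > 0.5)
    msg <- c(msg, "min_het_ab must lie in [0, 0.5]")
  if (length(object@require_pass) != 1L || is.na(object@require_pass))
    msg <- c(msg, "require_pass must be TRUE or FALSE")
  if (length(object@strict_missing) != 1L || is.na(object@strict_missing))
    msg <- c(msg, "strict_missing must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' @rdname QualityThresholds-class
#' @param min_dp,min_gq,min_het_ab,require_pass,strict_missing see slots.
#' @return A \code{QualityThresholds} object.
#' @export
qualityThresholds <- function(min_dp = 20, min_gq = 20, min_het_ab = 0.2,
                              require_pass = TRUE, strict_missing = TRUE) {
  new("QualityThresholds", min_dp = as.numeric(min_dp),
      min_gq = as.numeric(min_gq), min_het_ab = as.numeric(min_het_ab),
      require_pass = require_pass, strict_missing = strict_missing)
}

setMethod("show", "QualityThresholds", function(object) {
  cat("QualityThresholds: DP >=", object@min_dp, "| GQ >=", object@min_gq,
      "| het AB >=", object@min_het_ab,
      "| FILTER==PASS:", object@require_pass,
      "| strict missing:", object@strict_missing, "\n")
})

#' Noise and representation profile of one synthetic variant caller
#'
#' Describes how one synthetic caller corrupts the truth set: false-negative
#' probability per truth variant, expected false positives per sample
#' (Poisson), the representation dialect it emits, and its depth / genotype
#' quality models.
#'
#' @slot caller_id character(1) label, e.g. "varscan".
#' @slot fn_rate numeric(1) in \[0,1\]: probability a carried truth variant is
#'   dropped from this caller's output.
#' @slot fp_rate numeric(1) >= 0: Poisson mean of spurious calls per sample.
#' @slot representation_style one of "minimal" (normalized records),
#'   "right_shifted" (indels shifted to their right-most equivalent
#'   position), "multiallelic_merged" (het SNVs rendered with a decoy second
#'   alternate allele).
#' @slot depth_mean,depth_dispersion negative-binomial DP model
#'   (\code{rnbinom(mu = depth_mean, size = depth_dispersion)}).
#' @slot depth_min integer(1): lower truncation applied to sampled depths.
#' @slot gq_mean,gq_sd normal GQ model, truncated into \[0, 99\].
#' @slot nonpass_fraction numeric(1): fraction of records flagged with a
#'   non-PASS FILTER value.
#' @export
setClass("CallerProfile",
  representation(caller_id = "character", fn_rate = "numeric",
                 fp_rate = "numeric", representation_style = "character",
                 depth_mean = "numeric", depth_dispersion = "numeric",
                 depth_min = "numeric", gq_mean = "numeric", gq_sd = "numeric",
                 nonpass_fraction = "numeric"))

setValidity("CallerProfile", function(object) {
  msg <- character()
  if (object@fn_rate < 0 || object@fn_rate > 1)
    msg <- c(msg, "fn_rate must lie in [0,1]")
  if (object@fp_rate < 0) msg <- c(msg, "fp_rate must be >= 0")
  if (!object@representation_style %in%
      c("minimal", "right_shifted", "multiallelic_merged"))
    msg <- c(msg, "unknown representation_style")
  if (object@nonpass_fraction < 0 || object@nonpass_fraction > 1)
    msg <- c(msg, "nonpass_fraction must lie in [0,1]")
  if (object@depth_mean <= 0 || object@depth_dispersion <= 0)
    msg <- c(msg, "depth model parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname CallerProfile-class
#' @param caller_id,fn_rate,fp_rate,representation_style see slots.
#' @param depth_mean,depth_dispersion,depth_min,gq_mean,gq_sd,nonpass_fraction
#'   see slots.
#' @return A \code{CallerProfile}.
#' @export
callerProfile <- function(caller_id, fn_rate = 0, fp_rate = 0,
                          representation_style = "minimal",
                          depth_mean = 110, depth_dispersion = 5,
                          depth_min = 1, gq_mean = 80, gq_sd = 10,
                          nonpass_fraction = 0) {
  new("CallerProfile", caller_id = caller_id, fn_rate = as.numeric(fn_rate),
      fp_rate = as.numeric(fp_rate),
      representation_style = representation_style,
      depth_mean = as.numeric(depth_mean),
      depth_dispersion = as.numeric(depth_dispersion),
      depth_min = as.numeric(depth_min), gq_mean = as.numeric(gq_mean),
      gq_sd = as.numeric(gq_sd),
      nonpass_fraction = as.numeric(nonpass_fraction))
}

setMethod("show", "CallerProfile", function(object) {
  cat(sprintf(
    "CallerProfile '%s': fn=%.3g fp=%.3g style=%s DP~NB(mu=%g,size=%g,min=%g) GQ~N(%g,%g) nonPASS=%.3g\n",
    object@caller_id, object@fn_rate, object@fp_rate,
    object@representation_style, object@depth_mean, object@depth_dispersion,
    object@depth_min, object@gq_mean, object@gq_sd, object@nonpass_fraction))
})

#' Configuration of the synthetic cohort generator
#'
#' Fixes the study conditions the generator emulates: cohort composition
#' (49 samples, 30 labeled malignant, 5 BPH; the remainder are unlabeled
#' fresh-frozen blocks treated as malignant by default), the Gleason
#' grade-pattern distribution, the number of germline and somatic truth
#' variants, and how germline variants are shared across samples.
#'
#' @slot n_samples,n_malignant,n_bph integer counts.
#' @slot unlabeled_policy "malignant" (default) or "exclude" for the
#'   n_samples - n_malignant - n_bph unlabeled samples.
#' @slot gleason_distribution named numeric: probability of each malignant
#'   grade pattern ("primary+secondary", score >= 6).
#' @slot bph_gleason_distribution named numeric over patterns with score < 6.
#' @slot n_germline_truth,n_somatic_truth integer counts of truth variants.
#' @slot sharing_distribution named numeric: probability that a germline
#'   truth variant is carried by k samples, names are k in 2..n_samples.
#' @slot somatic_carrier_range integer(2): carrier-count range for somatic
#'   truth variants (carriers are always malignant samples).
#' @slot germline_hom_fraction numeric(1): probability a germline carrier is
#'   homozygous for the alternate allele.
#' @slot indel_fraction numeric(1): fraction of truth variants that are
#'   short indels (1-5 bp) rather than SNVs.
#' @slot contig_lengths named integer: toy reference contigs to simulate.
#' @slot seed integer(1): fully determines every generator output.
#' @export
setClass("CohortConfig",
  representation(n_samples = "integer", n_malignant = "integer",
                 n_bph = "integer", unlabeled_policy = "character",
                 gleason_distribution = "numeric",
                 bph_gleason_distribution = "numeric",
                 n_germline_truth = "integer", n_somatic_truth = "integer",
                 sharing_distribution = "numeric",
                 somatic_carrier_range = "integer",
                 germline_hom_fraction = "numeric",
                 indel_fraction = "numeric",
                 contig_lengths = "integer", seed = "integer"))

.checkDistribution <- function(x, what) {
  msg <- character()
  if (!length(x) || is.null(names(x)) || any(!nzchar(names(x))))
    msg <- c(msg, paste0(what, " must be a named probability vector"))
  else {
    if (any(x < 0)) msg <- c(msg, paste0(what, " has negative probabilities"))
    if (abs(sum(x) - 1) > 1e-9)
      msg <- c(msg, paste0(what, " probabilities must sum to 1 (got ",
                           format(sum(x)), ")"))
  }
  msg
}

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@n_malignant + object@n_bph > object@n_samples)
    msg <- c(msg, "n_malignant + n_bph must not exceed n_samples")
  if (!object@unlabeled_policy %in% c("malignant", "exclude"))
    msg <- c(msg, "unlabeled_policy must be 'malignant' or 'exclude'")
  msg <- c(msg, .checkDistribution(object@gleason_distribution,
                                   "gleason_distribution"))
  msg <- c(msg, .checkDistribution(object@bph_gleason_distribution,
                                   "bph_gleason_distribution"))
  msg <- c(msg, .checkDistribution(object@sharing_distribution,
                                   "sharing_distribution"))
  ks <- suppressWarnings(as.integer(names(object@sharing_distribution)))
  if (any(is.na(ks)) || any(ks < 2) || any(ks > object@n_samples))
    msg <- c(msg, "sharing_distribution names must be counts in 2..n_samples")
  gl <- strsplit(names(object@gleason_distribution), "+", fixed = TRUE)
  if (any(lengths(gl) != 2L))
    msg <- c(msg, "gleason_distribution names must look like '4+3'")
  if (length(object@somatic_carrier_range) != 2L ||
      object@somatic_carrier_range[1] < 1 ||
      diff(object@somatic_carrier_range) < 0)
    msg <- c(msg, "somatic_carrier_range must be an increasing integer pair")
  if (object@germline_hom_fraction < 0 || object@germline_hom_fraction > 1)
    msg <- c(msg, "germline_hom_fraction must lie in [0,1]")
  if (object@indel_fraction < 0 || object@indel_fraction > 1)
    msg <- c(msg, "indel_fraction must lie in [0,1]")
  if (!length(object@contig_lengths) || is.null(names(object@contig_lengths)))
    msg <- c(msg, "contig_lengths must be a named integer vector")
  if (length(msg)) msg else TRUE
})

#' @rdname CohortConfig-class
#' @param n_samples,n_malignant,n_bph,unlabeled_policy see slots.
#' @param gleason_distribution,bph_gleason_distribution see slots.
#' @param n_germline_truth,n_somatic_truth,sharing_distribution see slots.
#' @param somatic_carrier_range,germline_hom_fraction,indel_fraction see slots.
#' @param contig_lengths,seed see slots.
#' @return A \code{CohortConfig}.
#' @export
cohortConfig <- function(n_samples = 49L, n_malignant = 30L, n_bph = 5L,
                         unlabeled_policy = "malignant",
                         gleason_distribution = c("3+3" = 0.25, "3+4" = 0.25,
                                                  "4+3" = 0.20, "4+4" = 0.20,
                                                  "4+5" = 0.10),
                         bph_gleason_distribution = c("2+3" = 0.5,
                                                      "3+2" = 0.5),
                         n_germline_truth = 200L, n_somatic_truth = 12L,
                         sharing_distribution = NULL,
                         somatic_carrier_range = c(2L, 6L),
                         germline_hom_fraction = 0.3,
                         indel_fraction = 0.15,
                         contig_lengths = c(chr1 = 250000L, chr2 = 250000L),
                         seed = 1L) {
  if (is.null(sharing_distribution)) {
    ks <- 2:n_samples
    sharing_distribution <- stats::setNames(rep(1 / length(ks), length(ks)),
                                            as.character(ks))
  }
  new("CohortConfig", n_samples = as.integer(n_samples),
      n_malignant = as.integer(n_malignant), n_bph = as.integer(n_bph),
      unlabeled_policy = unlabeled_policy,
      gleason_distribution = gleason_distribution,
      bph_gleason_distribution = bph_gleason_distribution,
      n_germline_truth = as.integer(n_germline_truth),
      n_somatic_truth = as.integer(n_somatic_truth),
      sharing_distribution = sharing_distribution,
      somatic_carrier_range = as.integer(somatic_carrier_range),
      germline_hom_fraction = as.numeric(germline_hom_fraction),
      indel_fraction = as.numeric(indel_fraction),
      contig_lengths = stats::setNames(as.integer(contig_lengths),
                                       names(contig_lengths)),
      seed = as.integer(seed))
}

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: %d samples (%d malignant, %d BPH, remainder '%s'), %d germline + %d somatic truth variants, seed %d\n",
    object@n_samples, object@n_malignant, object@n_bph,
    object@unlabeled_policy, object@n_germline_truth,
    object@n_somatic_truth, object@seed))
})

#' Bona fide CNV filter configuration
#'
#' A cohort copy-number variant is called bona fide when its best-overlapping
#' population structural variant is demonstrably rare: the upper bound of the
#' score-based (Wilson) confidence interval of the population allele
#' frequency, at level \code{ci_level}, lies below \code{maf_threshold}
#' (falling back to the point frequency when allele counts are unavailable).
#'
#' @slot maf_threshold numeric(1) in (0,1); default 0.02.
#' @slot ci_level numeric(1) in (0,1); default 0.90.
#' @slot min_overlap_bp numeric(1) >= 1; default 1 (any overlap).
#' @slot reciprocal_fraction numeric(1) in (0,1\] or NA (default: off).
#' @export
setClass("BonaFideConfig",
  representation(maf_threshold = "numeric", ci_level = "numeric",
                 min_overlap_bp = "numeric", reciprocal_fraction = "numeric"))

setValidity("BonaFideConfig", function(object) {
  msg <- character()
  if (object@maf_threshold <= 0 || object@maf_threshold >= 1)
    msg <- c(msg, "maf_threshold must lie in (0,1)")
  if (object@ci_level <= 0 || object@ci_level >= 1)
    msg <- c(msg, "ci_level must lie in (0,1)")
  if (object@min_overlap_bp < 1)
    msg <- c(msg, "min_overlap_bp must be >= 1")
  if (!is.na(object@reciprocal_fraction) &&
      (object@reciprocal_fraction <= 0 || object@reciprocal_fraction > 1))
    msg <- c(msg, "reciprocal_fraction must lie in (0,1] or be NA")
  if (length(msg)) msg else TRUE
})

#' @rdname BonaFideConfig-class
#' @param maf_threshold,ci_level,min_overlap_bp,reciprocal_fraction see slots.
#' @return A \code{BonaFideConfig}.
#' @export
bonaFideConfig <- function(maf_threshold = 0.02, ci_level = 0.90,
                           min_overlap_bp = 1, reciprocal_fraction = NA_real_) {
  new("BonaFideConfig", maf_threshold = as.numeric(maf_threshold),
      ci_level = as.numeric(ci_level),
      min_overlap_bp = as.numeric(min_overlap_bp),
      reciprocal_fraction = as.numeric(reciprocal_fraction))
}

setMethod("show", "BonaFideConfig", function(object) {
  cat(sprintf(
    "BonaFideConfig: Wilson %g%% upper bound < %g, overlap >= %g bp, reciprocal = %s\n",
    100 * object@ci_level, object@maf_threshold, object@min_overlap_bp,
    ifelse(is.na(object@reciprocal_fraction), "off",
           format(object@reciprocal_fraction))))
})

#' Support thresholds for CAG-repeat allele calling and mosaicism
#'
#' @slot min_reads_per_allele numeric(1): spanning reads required to support
#'   an allele length; default 3 (suppresses single-read stutter).
#' @slot min_allele_fraction numeric(1) in (0,1): minimum fraction of
#'   spanning reads per supported allele; default 0.2.
#' @slot short_threshold numeric(1): repeat count at or below which a
#'   supported allele is high risk; default 18 (inclusive).
#' @slot min_total_spanning numeric(1): spanning reads below which a sample
#'   is uncallable; default 10.
#' @export
setClass("MosaicismParams",
  representation(min_reads_per_allele = "numeric",
                 min_allele_fraction = "numeric",
                 short_threshold = "numeric",
                 min_total_spanning = "numeric"))

setValidity("MosaicismParams", function(object) {
  msg <- character()
  if (object@min_reads_per_allele < 1)
    msg <- c(msg, "min_reads_per_allele must be >= 1")
  if (object@min_allele_fraction <= 0 || object@min_allele_fraction >= 1)
    msg <- c(msg, "min_allele_fraction must lie in (0,1)")
  if (object@short_threshold < 1)
    msg <- c(msg, "short_threshold must be >= 1")
  if (object@min_total_spanning < 1)
    msg <- c(msg, "min_total_spanning must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname MosaicismParams-class
#' @param min_reads_per_allele,min_allele_fraction see slots.
#' @param short_threshold,min_total_spanning see slots.
#' @return A \code{MosaicismParams}.
#' @export
mosaicismParams <- function(min_reads_per_allele = 3,
                            min_allele_fraction = 0.2,
                            short_threshold = 18, min_total_spanning = 10) {
  new("MosaicismParams",
      min_reads_per_allele = as.numeric(min_reads_per_allele),
      min_allele_fraction = as.numeric(min_allele_fraction),
      short_threshold = as.numeric(short_threshold),
      min_total_spanning = as.numeric(min_total_spanning))
}

setMethod("show", "MosaicismParams", function(object) {
  cat(sprintf(
    "MosaicismParams: allele support >= %g reads and >= %g fraction; short allele <= %g; callable at >= %g spanning reads\n",
    object@min_reads_per_allele, object@min_allele_fraction,
    object@short_threshold, object@min_total_spanning))
})

#' Definition of a flank-anchored tandem-repeat locus
#'
#' The repeat caller counts exact copies of \code{unit} enclosed between an
#' exact match of \code{left_flank} and a downstream exact match of
#' \code{right_flank}. Flanks must be at least 10 bases and must not end
#' (respectively begin) with a full copy of the unit, so the repeat tract
#' boundary is unambiguous.
#'
#' @slot contig character(1): contig the locus lives on (informational).
#' @slot unit character(1): repeat unit, default "CAG".
#' @slot left_flank,right_flank character(1): anchor sequences.
#' @export
setClass("RepeatLocus",
  representation(contig = "character", unit = "character",
                 left_flank = "character", right_flank = "character"))

setValidity("RepeatLocus", function(object) {
  msg <- character()
  u <- object@unit
  if (nchar(u) < 1) msg <- c(msg, "unit must be non-empty")
  if (nchar(object@left_flank) < 10 || nchar(object@right_flank) < 10)
    msg <- c(msg, "flanks must be at least 10 bases")
  lf <- object@left_flank; rf <- object@right_flank
  if (nchar(lf) >= nchar(u) &&
      substr(lf, nchar(lf) - nchar(u) + 1L, nchar(lf)) == u)
    msg <- c(msg, "left_flank must not end with a full copy of the unit")
  if (nchar(rf) >= nchar(u) && substr(rf, 1L, nchar(u)) == u)
    msg <- c(msg, "right_flank must not begin with a full copy of the unit")
  if (length(msg)) msg else TRUE
})

#' @rdname RepeatLocus-class
#' @param contig,unit,left_flank,right_flank see slots.
#' @return A \code{RepeatLocus}.
#' @export
repeatLocus <- function(contig = "chrX", unit = "CAG",
                        left_flank = "GATTACACGGTAGGTACCTG",
                        right_flank = "CCTTGAACGAGTTCGGGATC") {
  new("RepeatLocus", contig = contig, unit = unit,
      left_flank = left_flank, right_flank = right_flank)
}

setMethod("show", "RepeatLocus", function(object) {
  cat(sprintf("RepeatLocus on %s: %s...(%s)xN...%s\n", object@contig,
              object@left_flank, object@unit, object@right_flank))
})

## ---------------------------------------------------------------------------
## Data classes
## ---------------------------------------------------------------------------

#' A fully specified synthetic cohort
#'
#' Produced by \code{\link{simulateTruth}}. Holds the truth variant table,
#' the long genotype table (one row per variant carrier), the sample
#' metadata, the simulated reference and the generating configuration.
#'
#' @slot truth data.frame: one row per truth variant (contig, position, ref,
#'   alt, key, origin, classification, gnomad_maf, gip_aaf, n_carriers).
#' @slot genotypes data.frame: key, sample_id, genotype ("het"/"hom_alt").
#' @slot samples data.frame: sample metadata (see \code{\link{sampleMetadata}}).
#' @slot reference \code{Biostrings::DNAStringSet} toy reference.
#' @slot config the generating \code{CohortConfig}.
#' @export
setClass("SyntheticCohort",
  representation(truth = "data.frame", genotypes = "data.frame",
                 samples = "data.frame", reference = "ANY",
                 config = "CohortConfig"))

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d samples, %d truth variants (%d germline, %d somatic) on %d contigs\n",
    nrow(object@samples), nrow(object@truth),
    sum(object@truth$origin == "germline"),
    sum(object@truth$origin == "somatic"),
    length(object@reference)))
})

#' @describeIn SyntheticCohort-class truth variant table.
#' @param x a \code{SyntheticCohort}.
#' @export
truthVariants <- function(x) x@truth

#' @describeIn SyntheticCohort-class long genotype table (key, sample_id,
#'   genotype).
#' @export
truthGenotypes <- function(x) x@genotypes

#' @describeIn SyntheticCohort-class sample metadata table.
#' @export
cohortSamples <- function(x) x@samples

#' @describeIn SyntheticCohort-class simulated reference
#'   (\code{DNAStringSet}).
#' @export
cohortReference <- function(x) x@reference

#' Per-sample CAG repeat-length profile
#'
#' Produced by \code{\link{buildRepeatProfile}}: the histogram of repeat
#' counts over spanning reads, the allele lengths passing support thresholds,
#' the mosaicism flag (>= 2 supported alleles) and the short-allele risk
#' class.
#'
#' @slot sample character(1) sample id.
#' @slot histogram named integer: spanning-read count per repeat length.
#' @slot supported_alleles integer: repeat lengths passing support thresholds.
#' @slot mosaic logical(1).
#' @slot risk "high", "not-elevated" or "uncallable".
#' @slot n_spanning,n_nonspanning integer read counts.
#' @export
setClass("RepeatProfile",
  representation(sample = "character", histogram = "integer",
                 supported_alleles = "integer", mosaic = "logical",
                 risk = "character", n_spanning = "integer",
                 n_nonspanning = "integer"))

setValidity("RepeatProfile", function(object) {
  msg <- character()
  if (!object@risk %in% c("high", "not-elevated", "uncallable"))
    msg <- c(msg, "risk must be high, not-elevated or uncallable")
  if (length(object@supported_alleles) &&
      !all(as.character(object@supported_alleles) %in%
           names(object@histogram)))
    msg <- c(msg, "supported_alleles must be histogram keys")
  if (!identical(object@mosaic, length(object@supported_alleles) >= 2L) &&
      object@risk != "uncallable")
    msg <- c(msg, "mosaic flag must equal (>= 2 supported alleles)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RepeatProfile", function(object) {
  h <- paste(sprintf("%s:%d", names(object@histogram), object@histogram),
             collapse = " ")
  cat(sprintf(
    "RepeatProfile %s: %d spanning / %d non-spanning reads | %s | alleles {%s} | mosaic=%s | risk=%s\n",
    object@sample, object@n_spanning, object@n_nonspanning,
    ifelse(nzchar(h), h, "-"),
    paste(object@supported_alleles, collapse = ","),
    object@mosaic, object@risk))
})

#' @describeIn RepeatProfile-class supported allele lengths.
#' @param x a \code{RepeatProfile}.
#' @export
supportedAlleles <- function(x) x@supported_alleles

#' @describeIn RepeatProfile-class mosaicism flag.
#' @export
isMosaic <- function(x) x@mosaic

#' @describeIn RepeatProfile-class risk class.
#' @export
riskClass <- function(x) x@risk

#' @describeIn RepeatProfile-class spanning-read histogram.
#' @export
repeatHistogram <- function(x) x@histogram
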