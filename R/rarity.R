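## Population-frequency joins (gnomAD-like MAF, GenomeIndia-like AAF),
## rarity binning on the gnomAD MAF, and GWAS-catalog key matching.

#' Load a population frequency table
#'
#' TSV with header contig, position, ref, alt, frequency. "NR", "NA" and
#' empty strings parse as not-reported; numeric values outside \[0,1\] reject
#' the row with a warning.
#'
#' @param path TSV file.
#' @return data.frame with columns contig, position, ref, alt, frequency
#'   (NA = not reported) and key.
#' @export
loadFrequencyTable <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  required <- c("contig", "position", "ref", "alt", "frequency")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    .stopf("frequency table %s lacks column(s): %s", path,
           paste(missing_cols, collapse = ", "))
  tab$position <- as.integer(tab$position)
  raw <- trimws(tab$frequency)
  nr <- raw %in% c("NR", "NA", "", ".") | is.na(raw)
  freq <- suppressWarnings(as.numeric(raw))
  freq[nr] <- NA_real_
  malformed <- !nr & (is.na(freq) | freq < 0 | freq > 1)
  if (any(malformed)) {
    .warnf("rejecting %d frequency row(s) outside [0,1] or unparseable (rows %s)",
           sum(malformed),
           paste(utils::head(which(malformed), 10L), collapse = ", "))
    tab <- tab[!malformed, , drop = FALSE]
    freq <- freq[!malformed]
  }
  tab$frequency <- freq
  tab$key <- variantKey(tab$contig, tab$position, tab$ref, tab$alt)
  rownames(tab) <- NULL
  tab[, c("contig", "position", "ref", "alt", "frequency", "key")]
}

#' Join variants to gnomAD-like and GenomeIndia-like frequency tables
#'
#' Exact (contig, position, ref, alt) key joins, each column independent;
#' keys absent from a table come back as not-reported (NA). The GIP column is
#' an alternative-allele frequency carried for context; rarity binning uses
#' the gnomAD MAF only.
#'
#' @param variants data.frame with a \code{key} column (or contig, position,
#'   ref, alt).
#' @param gnomad,gip frequency tables from \code{\link{loadFrequencyTable}}
#'   (either may be NULL).
#' @return \code{variants} with added \code{gnomad_maf} and \code{gip_aaf}.
#' @export
joinFrequencies <- function(variants, gnomad = NULL, gip = NULL) {
  if (is.null(variants$key))
    variants$key <- variantKey(variants$contig, variants$position,
                               variants$ref, variants$alt)
  variants$gnomad_maf <- if (!is.null(gnomad) && nrow(gnomad))
    gnomad$frequency[match(variants$key, gnomad$key)] else NA_real_
  variants$gip_aaf <- if (!is.null(gip) && nrow(gip))
    gip$frequency[match(variants$key, gip$key)] else NA_real_
  variants
}

#' Bin a population MAF into rarity classes
#'
#' extremely_rare iff MAF <= \code{extreme_threshold} (inclusive boundary),
#' common iff MAF >= \code{common_threshold}, rare otherwise, not_reported
#' when the MAF is absent. The 0.001 extreme boundary follows the study's
#' rule; the 0.05 common boundary is the conventional common-variant cutoff
#' and is configurable.
#'
#' @param maf numeric vector of minor-allele frequencies (NA = not reported).
#' @param extreme_threshold default 0.001 (inclusive).
#' @param common_threshold default 0.05 (inclusive).
#' @return character vector over \{extremely_rare, rare, common,
#'   not_reported\}.
#' @examples
#' classifyRarity(c(6.23e-07, 0.001, 0.38, NA))
#' @export
classifyRarity <- function(maf, extreme_threshold = 0.001,
                           common_threshold = 0.05) {
  stopifnot(extreme_threshold < common_threshold)
  ifelse(is.na(maf), "not_reported",
  ifelse(maf <= extreme_threshold, "extremely_rare",
  ifelse(maf >= common_threshold, "common", "rare")))
}

#' Load a GWAS catalog table
#'
#' TSV with header contig, position, ref, alt, p_value, trait. p-values must
#' lie in (0, 1\]; offending rows are rejected with a warning.
#'
#' @param path TSV file.
#' @return data.frame with a \code{key} column.
#' @export
loadGwasCatalog <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  required <- c("contig", "position", "ref", "alt", "p_value")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    .stopf("GWAS catalog %s lacks column(s): %s", path,
           paste(missing_cols, collapse = ", "))
  tab$position <- as.integer(tab$position)
  tab$p_value <- suppressWarnings(as.numeric(tab$p_value))
  if (is.null(tab$trait)) tab$trait <- NA_character_
  bad <- is.na(tab$p_value) | tab$p_value <= 0 | tab$p_value > 1
  if (any(bad)) {
    .warnf("rejecting %d GWAS row(s) with p-values outside (0,1]", sum(bad))
    tab <- tab[!bad, , drop = FALSE]
  }
  tab$key <- variantKey(tab$contig, tab$position, tab$ref, tab$alt)
  rownames(tab) <- NULL
  tab[, c("contig", "position", "ref", "alt", "p_value", "trait", "key")]
}

#' Match variants against a GWAS catalog
#'
#' Strict exact match on all four key fields (chromosome, position, reference
#' and alternate allele); no allele flipping is attempted.
#'
#' @param variants data.frame with a \code{key} column (or the four key
#'   fields).
#' @param catalog data.frame from \code{\link{loadGwasCatalog}}.
#' @return the matching rows of \code{variants} with \code{gwas_p_value} and
#'   \code{gwas_trait} attached.
#' @export
matchGwas <- function(variants, catalog) {
  if (is.null(variants$key))
    variants$key <- variantKey(variants$contig, variants$position,
                               variants$ref, variants$alt)
  idx <- match(variants$key, catalog$key)
  hits <- variants[!is.na(idx), , drop = FALSE]
  hits$gwas_p_value <- catalog$p_value[idx[!is.na(idx)]]
  hits$gwas_trait <- catalog$trait[idx[!is.na(idx)]]
  hits
}

#' Summary counts over frequency records
#'
#' Emits the counting summary used for reporting: total records, count per
#' rarity bin (the bins partition the records), gnomAD not-reported count,
#' and counts per clinical classification when provided.
#'
#' @param records data.frame with a \code{gnomad_maf} column (e.g. from
#'   \code{\link{joinFrequencies}}).
#' @param classifications optional character vector aligned with
#'   \code{records} rows.
#' @param extreme_threshold,common_threshold passed to
#'   \code{\link{classifyRarity}}.
#' @return named list: total, extremely_rare, rare, common, not_reported,
#'   gnomad_not_reported, by_classification (named integer vector).
#' @export
rarityReport <- function(records, classifications = NULL,
                         extreme_threshold = 0.001, common_threshold = 0.05) {
  bins <- classifyRarity(records$gnomad_maf, extreme_threshold,
                         common_threshold)
  counts <- table(factor(bins, levels = c("extremely_rare", "rare", "common",
                                          "not_reported")))
  by_class <- if (!is.null(classifications))
    table(factor(classifications,
                 levels = sort(unique(classificationVocabulary()))))
  else integer()
  list(total = nrow(records),
       extremely_rare = unname(counts[["extremely_rare"]]),
       rare = unname(counts[["rare"]]),
       common = unname(counts[["common"]]),
       not_reported = unname(counts[["not_reported"]]),
       gnomad_not_reported = sum(is.na(records$gnomad_maf)),
       by_classification = c(by_class))
}
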