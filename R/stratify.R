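## Cohort stratification: occurrence ranking (shared vs unique variants) and
## the zygosity-by-Gleason-grade association.

#' Build / validate sample metadata
#'
#' Accepts a data.frame or TSV path with columns sample_id, tissue
#' ("malignant"/"BPH"), gleason_primary, gleason_secondary and derives the
#' Gleason score (primary + secondary) and grade group: "high" for patterns
#' 4+4 and 4+3 exactly, "lower" otherwise (3+4 is lower). The study inclusion
#' rule (malignant iff score >= 6) is checked and violations raise a warning.
#'
#' @param x data.frame or TSV path.
#' @return data.frame with added \code{score} and \code{grade_group}.
#' @export
sampleMetadata <- function(x) {
  meta <- if (is.character(x))
    utils::read.delim(x, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  else as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("sample_id", "tissue", "gleason_primary", "gleason_secondary")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    .stopf("sample metadata lacks column(s): %s",
           paste(missing_cols, collapse = ", "))
  if (!all(meta$tissue %in% c("malignant", "BPH")))
    .stopf("tissue must be 'malignant' or 'BPH'")
  meta$gleason_primary <- as.integer(meta$gleason_primary)
  meta$gleason_secondary <- as.integer(meta$gleason_secondary)
  if (any(meta$gleason_primary < 1 | meta$gleason_primary > 5 |
          meta$gleason_secondary < 1 | meta$gleason_secondary > 5))
    .stopf("Gleason patterns must be integers in 1..5")
  meta$score <- meta$gleason_primary + meta$gleason_secondary
  meta$grade_group <- ifelse(
    (meta$gleason_primary == 4L & meta$gleason_secondary %in% c(3L, 4L)),
    "high", "lower")
  inconsistent <- (meta$tissue == "malignant") != (meta$score >= 6L)
  if (any(inconsistent))
    .warnf("%d sample(s) violate the inclusion rule (malignant iff Gleason score >= 6): %s",
           sum(inconsistent),
           paste(utils::head(meta$sample_id[inconsistent], 10L),
                 collapse = ", "))
  meta
}

#' Variant-by-sample presence matrix
#'
#' @param consensus per-sample consensus table (needs \code{key} and
#'   \code{sample} columns).
#' @param samples optional character vector fixing the column order/universe.
#' @return logical matrix, rows = variant keys, columns = sample ids.
#' @export
presenceMatrix <- function(consensus, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(consensus$sample))
  keys <- sort(unique(consensus$key))
  m <- matrix(FALSE, nrow = length(keys), ncol = length(samples),
              dimnames = list(keys, samples))
  m[cbind(match(consensus$key, keys), match(consensus$sample, samples))] <-
    TRUE
  m
}

#' Rank variants by occurrence across samples
#'
#' Orders variants by descending carrier count, ties broken by the
#' (contig, position, alt) tuple; variants in a single sample are "unique",
#' variants in two or more are "shared".
#'
#' @param presence logical matrix from \code{\link{presenceMatrix}} (rownames
#'   are variant keys).
#' @param shared_threshold minimum carriers for the "shared" category,
#'   default 2.
#' @return data.frame: key, contig, position, ref, alt, carrier_count,
#'   category, in rank order.
#' @export
rankOccurrence <- function(presence, shared_threshold = 2L) {
  stopifnot(is.logical(presence), !is.null(rownames(presence)))
  counts <- rowSums(presence)
  parsed <- .parseKey(rownames(presence))
  ord <- order(-counts, parsed$contig, parsed$position, parsed$alt)
  out <- data.frame(key = rownames(presence)[ord],
                    contig = parsed$contig[ord],
                    position = parsed$position[ord],
                    ref = parsed$ref[ord], alt = parsed$alt[ord],
                    carrier_count = as.integer(counts[ord]),
                    stringsAsFactors = FALSE)
  out$category <- ifelse(out$carrier_count >= shared_threshold, "shared",
                         "unique")
  rownames(out) <- NULL
  out
}

#' Zygosity-by-grade association per variant
#'
#' For each variant, builds the 2x2 table \{hom_alt, het\} x \{high-grade,
#' lower/BPH\} over its carriers (discordant-genotype carriers must be
#' excluded upstream), flags concordance with the expected pattern (all
#' high-grade carriers homozygous AND all lower-grade/BPH carriers
#' heterozygous) and attaches the two-sided exact conditional
#' (hypergeometric) p-value from \code{stats::fisher.test}.
#'
#' @param genotypes data.frame with columns key, sample, genotype
#'   ("het"/"hom_alt").
#' @param samples sample metadata from \code{\link{sampleMetadata}}.
#' @return data.frame per variant: key, hom_high, hom_lower, het_high,
#'   het_lower, n_carriers, concordant, p_value. Variants with zero carriers
#'   are skipped with a warning.
#' @export
zygosityGradeAssociation <- function(genotypes, samples) {
  stopifnot(all(c("key", "sample", "genotype") %in% names(genotypes)))
  keys_in <- unique(genotypes$key)
  genotypes <- genotypes[genotypes$genotype %in% c("het", "hom_alt"), ,
                         drop = FALSE]
  grp <- samples$grade_group[match(genotypes$sample, samples$sample_id)]
  if (anyNA(grp))
    .stopf("genotype table names sample(s) absent from metadata: %s",
           paste(utils::head(
             unique(genotypes$sample[is.na(grp)]), 5L), collapse = ", "))
  high <- grp == "high"
  keys <- keys_in
  rows <- lapply(keys, function(k) {
    sel <- genotypes$key == k
    if (!any(sel)) return(NULL)
    hom <- genotypes$genotype[sel] == "hom_alt"
    hi <- high[sel]
    tab <- matrix(c(sum(hom & hi), sum(hom & !hi),
                    sum(!hom & hi), sum(!hom & !hi)),
                  nrow = 2L, byrow = TRUE)
    concordant <- all(hom[hi]) && all(!hom[!hi])
    p <- stats::fisher.test(tab)$p.value
    data.frame(key = k, hom_high = tab[1, 1], hom_lower = tab[1, 2],
               het_high = tab[2, 1], het_lower = tab[2, 2],
               n_carriers = sum(sel), concordant = concordant, p_value = p,
               stringsAsFactors = FALSE)
  })
  skipped <- vapply(rows, is.null, TRUE)
  if (any(skipped))
    .warnf("skipped %d variant(s) with zero carriers", sum(skipped))
  out <- do.call(rbind, rows[!skipped])
  if (is.null(out))
    out <- data.frame(key = character(), hom_high = integer(),
                      hom_lower = integer(), het_high = integer(),
                      het_lower = integer(), n_carriers = integer(),
                      concordant = logical(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
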