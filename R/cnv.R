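## Structural-variant interval intersection (bedtools-intersect semantics via
## GenomicRanges) and the bona fide CNV filter: the best-overlapping
## population SV must be rare at the configured Wilson-bound threshold.
## SV tables are BED-convention 0-based half-open; SNV positions are 1-based
## and converted internally. No mixed conventions are exposed.

#' Read a BED-like structural-variant table
#'
#' TSV with header contig, start (0-based inclusive), end (exclusive),
#' sv_type, and optionally pop_maf, allele_count, allele_number ("NR"/"" =
#' not reported). Intervals with start >= end are malformed and raise an
#' error naming the row.
#'
#' @param path TSV file.
#' @param source "cohort" or "population" (recorded on each row).
#' @return data.frame of intervals.
#' @export
readSvTable <- function(path, source = c("cohort", "population")) {
  source <- match.arg(source)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  required <- c("contig", "start", "end")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    .stopf("SV table %s lacks column(s): %s", path,
           paste(missing_cols, collapse = ", "))
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  if (is.null(tab$sv_type)) tab$sv_type <- "CNV-other"
  num_or_na <- function(x) {
    if (is.null(x)) return(rep(NA_real_, nrow(tab)))
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    out[x %in% c("NR", "NA", "", ".")] <- NA_real_
    out
  }
  tab$pop_maf <- num_or_na(tab$pop_maf)
  tab$allele_count <- num_or_na(tab$allele_count)
  tab$allele_number <- num_or_na(tab$allele_number)
  bad <- tab$start >= tab$end
  if (any(bad))
    .stopf("malformed interval (start >= end) at row %d of %s",
           which(bad)[1L], path)
  tab$source <- source
  tab$sv_id <- sprintf("%s_%d", source, seq_len(nrow(tab)))
  rownames(tab) <- NULL
  tab
}

## 0-based half-open BED interval -> 1-based inclusive GRanges
#' @keywords internal
.svGRanges <- function(sv) {
  GenomicRanges::GRanges(sv$contig,
                         IRanges::IRanges(start = sv$start + 1L,
                                          end = sv$end))
}

#' Intersect cohort SVs with population SVs
#'
#' Reports every (cohort, population) interval pair overlapping by at least
#' \code{min_overlap_bp} bases (half-open adjacency does not overlap), with
#' the overlap length and the reciprocal fraction on each side. When
#' \code{config@reciprocal_fraction} is set, both fractions must reach it;
#' when \code{match_type} is TRUE, sv_type must agree.
#'
#' @param cohort,population interval data.frames from
#'   \code{\link{readSvTable}}.
#' @param config a \code{\link{bonaFideConfig}}.
#' @param match_type logical, default FALSE.
#' @return data.frame: cohort_idx, population_idx, cohort_id, population_id,
#'   contig, overlap_bp, frac_cohort, frac_population.
#' @export
intersectSvs <- function(cohort, population, config = bonaFideConfig(),
                         match_type = FALSE) {
  stopifnot(is(config, "BonaFideConfig"))
  empty <- data.frame(cohort_idx = integer(), population_idx = integer(),
                      cohort_id = character(), population_id = character(),
                      contig = character(), overlap_bp = numeric(),
                      frac_cohort = numeric(), frac_population = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(cohort) || !nrow(population)) return(empty)
  gc <- .svGRanges(cohort)
  gp <- .svGRanges(population)
  hits <- GenomicRanges::findOverlaps(gc, gp,
                                      minoverlap = config@min_overlap_bp)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gc)[qi],
                                           IRanges::ranges(gp)[si]))
  out <- data.frame(cohort_idx = qi, population_idx = si,
                    cohort_id = cohort$sv_id[qi],
                    population_id = population$sv_id[si],
                    contig = cohort$contig[qi],
                    overlap_bp = as.numeric(ov),
                    frac_cohort = ov / (cohort$end[qi] - cohort$start[qi]),
                    frac_population = ov / (population$end[si] -
                                            population$start[si]),
                    stringsAsFactors = FALSE)
  if (match_type)
    out <- out[cohort$sv_type[out$cohort_idx] ==
               population$sv_type[out$population_idx], , drop = FALSE]
  if (!is.na(config@reciprocal_fraction))
    out <- out[out$frac_cohort >= config@reciprocal_fraction &
               out$frac_population >= config@reciprocal_fraction, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bona fide filter on overlapped cohort CNVs
#'
#' A cohort CNV qualifies as bona fide iff its best-overlapping population SV
#' (largest overlap, ties to the first) is rare: when allele counts are
#' present, the upper bound of the \code{ci_level} Wilson confidence interval
#' of the population allele frequency lies strictly below
#' \code{maf_threshold}; otherwise the point \code{pop_maf} must be below the
#' threshold. Cohort CNVs whose best match carries no frequency information
#' are excluded with reason \code{no_frequency}; CNVs with no qualifying
#' overlap get reason \code{no_overlap}.
#'
#' @param pairs overlap pairs from \code{\link{intersectSvs}}.
#' @param cohort,population the interval tables the pairs index into.
#' @param config a \code{\link{bonaFideConfig}}.
#' @return data.frame, one row per cohort CNV: cohort_id, contig, start, end,
#'   sv_type, best_population_id, overlap_bp, pop_maf, ci_upper, bona_fide,
#'   reason.
#' @export
bonaFideFilter <- function(pairs, cohort, population,
                           config = bonaFideConfig()) {
  stopifnot(is(config, "BonaFideConfig"))
  n <- nrow(cohort)
  best_pop <- rep(NA_integer_, n)
  best_ov <- rep(NA_real_, n)
  if (nrow(pairs)) {
    ord <- order(pairs$cohort_idx, -pairs$overlap_bp, pairs$population_idx)
    p <- pairs[ord, , drop = FALSE]
    first <- !duplicated(p$cohort_idx)
    best_pop[p$cohort_idx[first]] <- p$population_idx[first]
    best_ov[p$cohort_idx[first]] <- p$overlap_bp[first]
  }
  maf <- population$pop_maf[best_pop]
  ac <- population$allele_count[best_pop]
  an <- population$allele_number[best_pop]
  have_counts <- !is.na(ac) & !is.na(an) & an > 0
  ## when only pop_maf and allele_number are given, reconstruct the count
  only_n <- !have_counts & !is.na(maf) & !is.na(an) & an > 0
  ac[only_n] <- round(maf[only_n] * an[only_n])
  have_counts <- have_counts | only_n
  ci_upper <- rep(NA_real_, n)
  ci_upper[have_counts] <- wilsonUpperBound(ac[have_counts], an[have_counts],
                                            config@ci_level)
  rare <- rep(NA, n)
  rare[have_counts] <- ci_upper[have_counts] < config@maf_threshold
  point_only <- !have_counts & !is.na(maf)
  rare[point_only] <- maf[point_only] < config@maf_threshold
  bona_fide <- !is.na(best_pop) & !is.na(rare) & rare
  reason <- rep("", n)
  reason[is.na(best_pop)] <- "no_overlap"
  reason[!is.na(best_pop) & is.na(rare)] <- "no_frequency"
  reason[!is.na(best_pop) & !is.na(rare) & !rare] <- "not_rare"
  data.frame(cohort_id = cohort$sv_id, contig = cohort$contig,
             start = cohort$start, end = cohort$end,
             sv_type = cohort$sv_type,
             best_population_id = population$sv_id[best_pop],
             overlap_bp = best_ov, pop_maf = maf, ci_upper = ci_upper,
             bona_fide = bona_fide, reason = reason,
             stringsAsFactors = FALSE)
}

#' Co-localize SNVs with CNV intervals
#'
#' A pair is reported iff the SNV position falls inside the half-open CNV
#' interval: start <= position < end, so a variant sitting exactly at the
#' exclusive end coordinate is outside.
#'
#' @param snvs data.frame with contig and position.
#' @param cnvs interval data.frame (BED convention, half-open) with contig,
#'   start, end.
#' @return data.frame of (snv_idx, cnv_idx) pairs with coordinates.
#' @export
snvInCnv <- function(snvs, cnvs) {
  empty <- data.frame(snv_idx = integer(), cnv_idx = integer(),
                      contig = character(), position = integer(),
                      cnv_start = numeric(), cnv_end = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(snvs) || !nrow(cnvs)) return(empty)
  gs <- GenomicRanges::GRanges(snvs$contig,
                               IRanges::IRanges(start = snvs$position,
                                                width = 1L))
  ## half-open in position space: covered coordinates are start .. end-1
  gcnv <- GenomicRanges::GRanges(cnvs$contig,
                                 IRanges::IRanges(start = cnvs$start,
                                                  end = cnvs$end - 1L))
  hits <- GenomicRanges::findOverlaps(gs, gcnv)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  data.frame(snv_idx = qi, cnv_idx = si, contig = snvs$contig[qi],
             position = snvs$position[qi], cnv_start = cnvs$start[si],
             cnv_end = cnvs$end[si], stringsAsFactors = FALSE)
}

#' Per-chromosome bona fide CNV counts
#'
#' Tabular substitute for an ideogram figure: counts of bona fide CNVs per
#' contig.
#'
#' @param bona data.frame from \code{\link{bonaFideFilter}}.
#' @return data.frame contig / n.
#' @export
cnvChromosomeCounts <- function(bona) {
  tab <- table(bona$contig[bona$bona_fide])
  data.frame(contig = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
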