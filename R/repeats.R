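## Flank-anchored CAG repeat-length estimation and somatic mosaicism calling.
## A read is "spanning" when it contains an exact left-flank match followed
## downstream by an exact right-flank match with a pure whole-number run of
## repeat units in between; everything else is non-spanning with a reason
## code. Interrupted tracts are deliberately discarded rather than guessed.

#' Count repeat units in reads
#'
#' @param reads character vector or \code{DNAStringSet}; names become read
#'   ids.
#' @param locus a \code{\link{repeatLocus}}.
#' @param sample sample id attached to every observation.
#' @return data.frame: sample, read_id, spanning (logical), repeat_count
#'   (NA unless spanning), reason ("" / no_left_flank / no_right_flank /
#'   interrupted).
#' @export
countRepeatUnits <- function(reads, locus = repeatLocus(),
                             sample = NA_character_) {
  stopifnot(is(locus, "RepeatLocus"))
  if (!is.character(reads)) reads <- as.character(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  n <- length(reads)
  if (!n)
    return(data.frame(sample = character(), read_id = character(),
                      spanning = logical(), repeat_count = integer(),
                      reason = character(), stringsAsFactors = FALSE))
  lf <- locus@left_flank; rf <- locus@right_flank; unit <- locus@unit
  ul <- nchar(unit)
  lpos <- regexpr(lf, reads, fixed = TRUE)
  reason <- rep("", n)
  count <- rep(NA_integer_, n)
  reason[lpos < 0L] <- "no_left_flank"
  search_from <- lpos + nchar(lf)
  tails <- substring(reads, search_from)
  rpos <- regexpr(rf, tails, fixed = TRUE)
  no_rf <- lpos > 0L & rpos < 0L
  reason[no_rf] <- "no_right_flank"
  ok <- lpos > 0L & rpos > 0L
  if (any(ok)) {
    enclosed <- substr(tails[ok], 1L, rpos[ok] - 1L)
    k <- nchar(enclosed) %/% ul
    pure <- nchar(enclosed) %% ul == 0L &
      enclosed == strrep(unit, k)
    idx <- which(ok)
    count[idx[pure]] <- k[pure]
    reason[idx[!pure]] <- "interrupted"
  }
  data.frame(sample = sample, read_id = ids, spanning = !is.na(count),
             repeat_count = count, reason = reason, stringsAsFactors = FALSE)
}

#' Build a per-sample repeat profile
#'
#' Histograms repeat counts over spanning reads and calls supported alleles:
#' a length is supported iff it has at least
#' \code{params@min_reads_per_allele} reads AND at least
#' \code{params@min_allele_fraction} of the spanning reads. A sample with
#' fewer than \code{params@min_total_spanning} spanning reads is uncallable.
#' Mosaicism = two or more supported alleles.
#'
#' @param observations data.frame from \code{\link{countRepeatUnits}} for one
#'   sample.
#' @param params a \code{\link{mosaicismParams}}.
#' @return a \code{\linkS4class{RepeatProfile}}.
#' @export
buildRepeatProfile <- function(observations, params = mosaicismParams()) {
  stopifnot(is(params, "MosaicismParams"))
  smp <- if (nrow(observations)) observations$sample[1L] else NA_character_
  span <- observations$repeat_count[observations$spanning]
  n_span <- length(span)
  n_non <- nrow(observations) - n_span
  hist <- table(span)
  histogram <- stats::setNames(as.integer(hist), names(hist))
  supported <- if (n_span > 0)
    as.integer(names(histogram)[histogram >= params@min_reads_per_allele &
                                histogram / n_span >=
                                  params@min_allele_fraction])
  else integer()
  uncallable <- n_span < params@min_total_spanning
  profile <- new("RepeatProfile", sample = as.character(smp),
                 histogram = histogram,
                 supported_alleles = sort(supported),
                 mosaic = length(supported) >= 2L,
                 risk = if (uncallable) "uncallable" else "not-elevated",
                 n_spanning = as.integer(n_span),
                 n_nonspanning = as.integer(n_non))
  profile@risk <- classifyRepeatRisk(profile, params)
  profile
}

#' Classify short-allele risk
#'
#' High risk iff any supported allele is at or below
#' \code{params@short_threshold} repeats (inclusive boundary, default 18);
#' not-elevated otherwise; uncallable profiles stay uncallable.
#'
#' @param profile a \code{RepeatProfile}.
#' @param params a \code{\link{mosaicismParams}}.
#' @return "high", "not-elevated" or "uncallable".
#' @export
classifyRepeatRisk <- function(profile, params = mosaicismParams()) {
  stopifnot(is(profile, "RepeatProfile"), is(params, "MosaicismParams"))
  if (profile@n_spanning < params@min_total_spanning) return("uncallable")
  if (length(profile@supported_alleles) &&
      any(profile@supported_alleles <= params@short_threshold)) "high"
  else "not-elevated"
}

#' Cohort mosaicism summary
#'
#' Fraction of mosaic samples among callable samples (and, since the
#' denominator convention is ambiguous in practice, also among all samples),
#' with an optional per-grade breakdown when sample metadata is supplied.
#'
#' @param profiles list of \code{RepeatProfile} objects.
#' @param samples optional metadata from \code{\link{sampleMetadata}}.
#' @return list: n_samples, n_callable, n_mosaic, fraction_mosaic_callable,
#'   fraction_mosaic_all, n_high_risk, by_grade (data.frame or NULL), empty
#'   (TRUE when no sample is callable).
#' @export
cohortMosaicismSummary <- function(profiles, samples = NULL) {
  stopifnot(length(profiles) >= 1L)
  callable <- vapply(profiles, function(p) p@risk != "uncallable", TRUE)
  mosaic <- vapply(profiles, function(p) p@mosaic, TRUE) & callable
  high <- vapply(profiles, function(p) p@risk == "high", TRUE)
  n_callable <- sum(callable)
  out <- list(n_samples = length(profiles), n_callable = n_callable,
              n_mosaic = sum(mosaic),
              fraction_mosaic_callable =
                if (n_callable > 0) sum(mosaic) / n_callable else NA_real_,
              fraction_mosaic_all = sum(mosaic) / length(profiles),
              n_high_risk = sum(high),
              by_grade = NULL, empty = n_callable == 0L)
  if (!is.null(samples)) {
    ids <- vapply(profiles, function(p) p@sample, "")
    grade <- samples$grade_group[match(ids, samples$sample_id)]
    df <- data.frame(grade_group = grade, callable = callable,
                     mosaic = mosaic, high_risk = high,
                     stringsAsFactors = FALSE)
    agg <- do.call(rbind, lapply(split(df, df$grade_group), function(d)
      data.frame(grade_group = d$grade_group[1L], n = nrow(d),
                 n_callable = sum(d$callable), n_mosaic = sum(d$mosaic),
                 n_high_risk = sum(d$high_risk), stringsAsFactors = FALSE)))
    rownames(agg) <- NULL
    out$by_grade <- agg
  }
  out
}

#' Serialize repeat profiles to a TSV-ready table
#'
#' @param profiles list of \code{RepeatProfile}.
#' @return data.frame: sample, n_spanning, n_nonspanning, histogram
#'   ("count:reads" pairs), supported_alleles, mosaic, risk.
#' @export
repeatProfileTable <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample = p@sample, n_spanning = p@n_spanning,
               n_nonspanning = p@n_nonspanning,
               histogram = paste(sprintf("%s:%d", names(p@histogram),
                                         p@histogram), collapse = ","),
               supported_alleles = paste(p@supported_alleles,
                                         collapse = ","),
               mosaic = p@mosaic, risk = p@risk, stringsAsFactors = FALSE)
  }))
}
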