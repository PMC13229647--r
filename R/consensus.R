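## Multi-caller consensus core: VCF reading, multiallelic splitting, variant
## normalization, quality filtering and the strict cross-caller intersection.
## Coordinates are VCF-style 1-based inclusive throughout this file; 0-based
## half-open conversions happen only at the BED boundary in the CNV module.

#' Read one caller's VCF into a raw call table
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) holding a single sample's calls
#' from one caller. FORMAT fields GT, DP, GQ and AD are extracted when
#' present; missing fields come back as NA and are handled downstream by
#' \code{\link{applyQualityFilters}}.
#'
#' @param path VCF file. When \code{caller}/\code{sample} are NULL they are
#'   parsed from a \code{<sample>.<caller>.vcf} filename.
#' @param caller,sample optional labels attached to every record.
#' @return data.frame with columns contig, position, ref, alt (comma-joined
#'   when multiallelic), filter, caller, sample, gt, dp, gq, ad.
#' @export
readCallerVcf <- function(path, caller = NULL, sample = NULL) {
  if (is.null(caller) || is.null(sample)) {
    base <- sub("\\.vcf(\\.gz)?$", "", basename(path))
    parts <- strsplit(base, ".", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      .stopf("cannot infer sample/caller from file name '%s'", basename(path))
    if (is.null(sample)) sample <- paste(parts[-length(parts)], collapse = ".")
    if (is.null(caller)) caller <- parts[length(parts)]
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n <- nrow(fix)
  empty <- data.frame(contig = character(), position = integer(),
                      ref = character(), alt = character(),
                      filter = character(), caller = character(),
                      sample = character(), gt = character(),
                      dp = numeric(), gq = numeric(), ad = character(),
                      stringsAsFactors = FALSE)
  if (is.null(n) || n == 0L) return(empty)
  getFmt <- function(el, as_num = FALSE) {
    out <- tryCatch(
      vcfR::extract.gt(vcf, element = el, as.numeric = as_num)[, 1L],
      error = function(e) rep(NA, n))
    unname(out)
  }
  data.frame(contig = unname(fix[, "CHROM"]),
             position = as.integer(fix[, "POS"]),
             ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"]),
             filter = unname(fix[, "FILTER"]),
             caller = caller, sample = sample,
             gt = as.character(getFmt("GT")),
             dp = as.numeric(getFmt("DP", TRUE)),
             gq = as.numeric(getFmt("GQ", TRUE)),
             ad = as.character(getFmt("AD")),
             stringsAsFactors = FALSE)
}

#' Split multiallelic records into biallelic ones
#'
#' One output record per alternate allele. AD is decomposed positionally into
#' \code{ad_ref} (the original reference depth, not rescaled) and the
#' retained alternate's depth; DP, GQ and FILTER are copied. The genotype is
#' recoded against the retained alternate: both alleles matching gives
#' \code{hom_alt}, one gives \code{het}; a het whose other allele is a
#' different alternate is flagged \code{cross_alt}.
#'
#' @param calls data.frame as returned by \code{\link{readCallerVcf}}.
#' @return data.frame with one row per (record, alt), adding columns
#'   \code{ad_ref}, \code{ad_alt}, \code{genotype} ("hom_alt", "het", "ref",
#'   "missing") and \code{cross_alt}.
#' @export
splitMultiallelic <- function(calls) {
  if (!nrow(calls)) {
    calls$ad_ref <- integer(); calls$ad_alt <- integer()
    calls$genotype <- character(); calls$cross_alt <- logical()
    return(calls)
  }
  alts <- strsplit(calls$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  if (any(n_alt < 1L)) .stopf("record with no alternate allele")
  ads <- strsplit(ifelse(is.na(calls$ad), "", calls$ad), ",", fixed = TRUE)
  has_ad <- !is.na(calls$ad)
  bad <- has_ad & lengths(ads) != n_alt + 1L
  if (any(bad)) {
    i <- which(bad)[1L]
    .stopf("malformed record at %s:%d: AD has %d values for %d alternate allele(s)",
           calls$contig[i], calls$position[i], lengths(ads)[i], n_alt[i])
  }
  idx <- rep.int(seq_len(nrow(calls)), n_alt)
  alt_i <- sequence(n_alt)
  out <- calls[idx, , drop = FALSE]
  rownames(out) <- NULL
  out$alt <- unlist(alts, use.names = FALSE)

  adnum <- lapply(ads, function(x) suppressWarnings(as.integer(x)))
  out$ad_ref <- ifelse(has_ad[idx],
                       vapply(seq_along(idx), function(j)
                         adnum[[idx[j]]][1L], 1L),
                       NA_integer_)
  out$ad_alt <- ifelse(has_ad[idx],
                       vapply(seq_along(idx), function(j)
                         adnum[[idx[j]]][alt_i[j] + 1L], 1L),
                       NA_integer_)

  gt_alleles <- strsplit(ifelse(is.na(calls$gt), ".", calls$gt), "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(gt_alleles, `[`, "", 1L)))
  a2raw <- vapply(gt_alleles, function(g)
    if (length(g) >= 2L) g[2L] else g[1L], "")
  a2 <- suppressWarnings(as.integer(a2raw))
  a1 <- a1[idx]; a2 <- a2[idx]
  n_match <- (!is.na(a1) & a1 == alt_i) + (!is.na(a2) & a2 == alt_i)
  genotype <- ifelse(is.na(a1) | is.na(a2), "missing",
              ifelse(n_match == 2L, "hom_alt",
              ifelse(n_match == 1L, "het", "ref")))
  other <- ifelse(!is.na(a1) & a1 == alt_i, a2, a1)
  out$genotype <- genotype
  out$cross_alt <- genotype == "het" & !is.na(other) & other != 0L &
    other != alt_i
  out
}

## normalize a single (pos, ref, alt) against one contig string; returns
## list(position, ref, alt). The classic trim/left-align loop: strip shared
## trailing bases (left-extending with the preceding reference base whenever
## an allele would otherwise empty), then strip shared leading bases.
#' @keywords internal
.normalizeOne <- function(seqchar, pos, ref, alt) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (substr(ref, nr, nr) != substr(alt, na, na)) break
    if (nr == 1L || na == 1L) {
      if (pos <= 1L)
        .stopf("left-alignment underflow at position 1 (ref '%s', alt '%s')",
               ref, alt)
      b <- substr(seqchar, pos - 1L, pos - 1L)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      pos <- pos - 1L
      nr <- nr + 1L; na <- na + 1L
    }
    ref <- substr(ref, 1L, nr - 1L)
    alt <- substr(alt, 1L, na - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(position = pos, ref = ref, alt = alt)
}

#' Normalize biallelic variants to their canonical representation
#'
#' Reduces every (contig, position, ref, alt) to the unique minimal
#' left-aligned form: shared suffixes are stripped (prepending the preceding
#' reference base whenever an allele would become empty, which walks indels
#' leftwards), then shared prefixes are stripped advancing the position, so
#' indels keep the mandatory single anchor base. The result is invariant to
#' the input representation and idempotent. The reference allele of every
#' input record is checked against the reference sequence.
#'
#' @param calls data.frame with columns contig, position, ref, alt (single
#'   allele per row); additional columns are carried through.
#' @param reference a \code{DNAStringSet} (or named character vector of
#'   contig sequences) covering all records.
#' @return \code{calls} with updated position/ref/alt plus a \code{key}
#'   column (\code{\link{variantKey}}).
#' @export
normalizeVariants <- function(calls, reference) {
  refchars <- .referenceAsStrings(reference)
  if (!nrow(calls)) {
    calls$key <- character()
    return(calls)
  }
  miss <- setdiff(unique(calls$contig), names(refchars))
  if (length(miss))
    .stopf("contig(s) absent from reference: %s", paste(miss, collapse = ", "))
  bad_allele <- !grepl("^[ACGTN]+$", calls$ref) | !grepl("^[ACGTN]+$", calls$alt)
  if (any(bad_allele)) {
    i <- which(bad_allele)[1L]
    .stopf("malformed alleles at %s:%d ('%s' > '%s')", calls$contig[i],
           calls$position[i], calls$ref[i], calls$alt[i])
  }
  obs <- substring(refchars[calls$contig], calls$position,
                   calls$position + nchar(calls$ref) - 1L)
  mismatch <- obs != calls$ref
  if (any(mismatch)) {
    i <- which(mismatch)[1L]
    .stopf("reference mismatch at %s:%d: VCF ref '%s' vs reference '%s'",
           calls$contig[i], calls$position[i], calls$ref[i], obs[i])
  }
  same <- calls$ref == calls$alt
  if (any(same)) {
    i <- which(same)[1L]
    .stopf("ref equals alt at %s:%d", calls$contig[i], calls$position[i])
  }
  ## fast path: 1 bp / 1 bp records are already minimal
  todo <- which(nchar(calls$ref) > 1L | nchar(calls$alt) > 1L)
  if (length(todo)) {
    pos <- calls$position; ref <- calls$ref; alt <- calls$alt
    for (i in todo) {
      res <- .normalizeOne(refchars[[calls$contig[i]]], pos[i], ref[i], alt[i])
      pos[i] <- res$position; ref[i] <- res$ref; alt[i] <- res$alt
    }
    calls$position <- pos; calls$ref <- ref; calls$alt <- alt
  }
  calls$key <- variantKey(calls$contig, calls$position, calls$ref, calls$alt)
  calls
}

#' Allelic balance from allele depths
#'
#' AB = alt depth / (ref depth + alt depth). Computed from AD rather than DP
#' so reads assigned to other alleles (or filtered from DP) do not distort
#' the ratio.
#'
#' @param ad_ref,ad_alt integer vectors.
#' @return numeric vector; NA where depths are missing or both zero.
#' @examples
#' computeAB(16, 4)   # 0.2
#' computeAB(0, 0)    # NA: unavailable at zero depth
#' @export
computeAB <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  ifelse(is.na(tot) | tot == 0, NA_real_, ad_alt / tot)
}

#' Apply per-record quality filters
#'
#' Evaluates every gate in \code{thresholds} and reports all failing reasons
#' (not just the first): \code{low_dp}, \code{low_gq}, \code{low_ab} (hets
#' only), \code{not_pass}, and \code{missing_field} when a required FORMAT
#' field is absent under strict mode.
#'
#' @param calls biallelic call table (from \code{\link{splitMultiallelic}}).
#' @param thresholds a \code{\link{qualityThresholds}} object.
#' @return \code{calls} with added \code{ab}, \code{pass} (logical) and
#'   \code{reasons} (semicolon-joined codes, "" when passing).
#' @export
applyQualityFilters <- function(calls, thresholds = qualityThresholds()) {
  stopifnot(is(thresholds, "QualityThresholds"))
  n <- nrow(calls)
  ab <- computeAB(calls$ad_ref, calls$ad_alt)
  is_het <- !is.na(calls$genotype) & calls$genotype == "het"
  flags <- list(
    not_pass = if (thresholds@require_pass)
      is.na(calls$filter) | calls$filter != "PASS" else rep(FALSE, n),
    missing_field = if (thresholds@strict_missing)
      is.na(calls$dp) | is.na(calls$gq) | (is_het & is.na(ab))
      else rep(FALSE, n),
    low_dp = !is.na(calls$dp) & calls$dp < thresholds@min_dp,
    low_gq = !is.na(calls$gq) & calls$gq < thresholds@min_gq,
    low_ab = is_het & !is.na(ab) & ab < thresholds@min_het_ab)
  reasons <- rep("", n)
  for (code in names(flags)) {
    f <- flags[[code]]
    reasons[f] <- ifelse(nzchar(reasons[f]), paste(reasons[f], code,
                                                   sep = ";"), code)
  }
  calls$ab <- ab
  calls$pass <- !nzchar(reasons)
  calls$reasons <- reasons
  calls
}

#' Strict cross-caller consensus
#'
#' Retains a (sample, contig, position, ref, alt) key iff it is present, with
#' an exact normalized match, in at least \code{required_callers} of the
#' caller sets (default: all callers seen in the input). Only carrier
#' genotypes (het / hom_alt) count as presence. The consensus genotype is the
#' majority vote across supporting callers; an exact tie keeps the key but
#' flags it \code{discordant_gt} with genotype NA, and such variants are
#' excluded from zygosity stratification downstream.
#'
#' @param calls normalized, quality-filtered biallelic call table with
#'   columns sample, caller, contig, position, ref, alt, key, genotype and
#'   (optionally) dp, gq, ab. Pass only records meant to enter the
#'   intersection (i.e. those with \code{pass == TRUE}).
#' @param required_callers integer; default all distinct callers in
#'   \code{calls}. Must not exceed that number.
#' @param n_caller_sets optional explicit number of caller sets (use when a
#'   caller's set can be legitimately empty).
#' @return data.frame: sample, contig, position, ref, alt, key, n_callers,
#'   callers (comma-joined), genotype, discordant_gt, min_dp, min_gq, ab
#'   (mean across supporting callers).
#' @export
consensusAcrossCallers <- function(calls, required_callers = NULL,
                                   n_caller_sets = NULL) {
  if (is.null(n_caller_sets))
    n_caller_sets <- length(unique(calls$caller))
  if (is.null(required_callers)) required_callers <- n_caller_sets
  if (n_caller_sets > 0 && required_callers > n_caller_sets)
    .stopf("required_callers (%d) exceeds the %d caller set(s) provided",
           required_callers, n_caller_sets)
  empty <- data.frame(sample = character(), contig = character(),
                      position = integer(), ref = character(),
                      alt = character(), key = character(),
                      n_callers = integer(), callers = character(),
                      genotype = character(), discordant_gt = logical(),
                      min_dp = numeric(), min_gq = numeric(), ab = numeric(),
                      stringsAsFactors = FALSE)
  keep <- !is.na(calls$genotype) & calls$genotype %in% c("het", "hom_alt")
  calls <- calls[keep, , drop = FALSE]
  if (!nrow(calls)) return(empty)
  for (col in c("dp", "gq", "ab"))
    if (is.null(calls[[col]])) calls[[col]] <- NA_real_
  dt <- data.table::as.data.table(
    calls[, c("sample", "caller", "contig", "position", "ref", "alt", "key",
              "genotype", "dp", "gq", "ab")])
  ## one vote per caller per key
  dt <- unique(dt, by = c("sample", "key", "caller"))
  minNA <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  cons <- dt[, {
    n_hom <- sum(genotype == "hom_alt")
    n_het <- sum(genotype == "het")
    list(contig = contig[1L], position = position[1L], ref = ref[1L],
         alt = alt[1L], n_callers = .N,
         callers = paste(sort(caller), collapse = ","),
         genotype = if (n_hom > n_het) "hom_alt"
                    else if (n_het > n_hom) "het" else NA_character_,
         discordant_gt = n_hom == n_het,
         min_dp = minNA(dp), min_gq = minNA(gq),
         ab = if (all(is.na(ab))) NA_real_ else mean(ab, na.rm = TRUE))
  }, by = c("sample", "key")]
  cons <- cons[cons$n_callers >= required_callers, ]
  out <- as.data.frame(cons, stringsAsFactors = FALSE)
  out <- out[, c("sample", "contig", "position", "ref", "alt", "key",
                 "n_callers", "callers", "genotype", "discordant_gt",
                 "min_dp", "min_gq", "ab")]
  out[order(out$sample, out$contig, out$position, out$alt), , drop = FALSE]
}

#' Run the per-sample consensus extraction over a VCF manifest
#'
#' Convenience wrapper chaining \code{\link{readCallerVcf}},
#' \code{\link{splitMultiallelic}}, \code{\link{normalizeVariants}},
#' \code{\link{applyQualityFilters}} and
#' \code{\link{consensusAcrossCallers}}, accumulating a filter-funnel report.
#' Stage order is normalize/split before quality filtering before
#' intersection; set \code{filter_after_consensus = TRUE} to intersect first
#' and filter afterwards for sensitivity analysis.
#'
#' @param manifest data.frame with columns path, sample, caller.
#' @param reference \code{DNAStringSet} or named character vector.
#' @param thresholds a \code{QualityThresholds}.
#' @param required_callers see \code{\link{consensusAcrossCallers}}.
#' @param filter_after_consensus logical, default FALSE.
#' @return list with \code{consensus} (data.frame), \code{funnel}
#'   (data.frame stage/type/n_in/n_out/reasons) and \code{filtered} (the
#'   per-caller filtered call table).
#' @export
extractConsensus <- function(manifest, reference,
                             thresholds = qualityThresholds(),
                             required_callers = NULL,
                             filter_after_consensus = FALSE) {
  stopifnot(all(c("path", "sample", "caller") %in% names(manifest)))
  raw <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i)
    readCallerVcf(manifest$path[i], caller = manifest$caller[i],
                  sample = manifest$sample[i])))
  funnel <- data.frame(stage = character(), type = character(),
                       n_in = integer(), n_out = integer(),
                       reasons = character(), stringsAsFactors = FALSE)
  addStage <- function(stage, type, n_in, n_out, reasons = "") {
    rbind(funnel, data.frame(stage = stage, type = type,
                             n_in = as.integer(n_in),
                             n_out = as.integer(n_out), reasons = reasons,
                             stringsAsFactors = FALSE))
  }
  funnel <- addStage("load_vcfs", "transform", nrow(raw), nrow(raw))
  bi <- splitMultiallelic(raw)
  funnel <- addStage("split_multiallelic", "transform", nrow(raw), nrow(bi))
  norm <- normalizeVariants(bi, reference)
  funnel <- addStage("normalize", "transform", nrow(bi), nrow(norm))
  n_caller_sets <- length(unique(manifest$caller))
  if (filter_after_consensus) {
    cons_all <- consensusAcrossCallers(norm, required_callers, n_caller_sets)
    funnel <- addStage("consensus", "filter", nrow(norm), nrow(cons_all),
                       .encodeReasons(c(below_required_callers =
                                          nrow(norm) - nrow(cons_all))))
    flt <- applyQualityFilters(norm, thresholds)
    filtered <- flt[flt$pass, , drop = FALSE]
    cons <- consensusAcrossCallers(filtered, required_callers, n_caller_sets)
    funnel <- addStage("quality_filter", "filter", nrow(cons_all), nrow(cons),
                       .encodeReasons(c(failed_quality =
                                          nrow(cons_all) - nrow(cons))))
  } else {
    flt <- applyQualityFilters(norm, thresholds)
    filtered <- flt[flt$pass, , drop = FALSE]
    funnel <- addStage("quality_filter", "filter", nrow(flt), nrow(filtered),
                       .encodeReasons(table(flt$reasons[!flt$pass])))
    cons <- consensusAcrossCallers(filtered, required_callers, n_caller_sets)
    funnel <- addStage("consensus", "filter", nrow(filtered), nrow(cons),
                       .encodeReasons(c(below_required_callers =
                                          nrow(filtered) - nrow(cons))))
  }
  list(consensus = cons, funnel = funnel, filtered = filtered)
}
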