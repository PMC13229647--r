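## Pipeline orchestration: chains consensus extraction, annotation matching,
## rarity binning, cohort stratification, CNV overlap and repeat profiling,
## maintaining a filter-funnel report across stages. Every tabular output is
## TSV with a header row; a JSON summary is written per run.

#' Validate a filter-funnel report
#'
#' Checks the funnel invariants: adjacent stages chain (records out of stage
#' k equal records into stage k+1), no filtering stage emits more records
#' than it received, and for filtering stages the per-reason counts account
#' exactly for the dropped records.
#'
#' @param funnel data.frame with columns stage, type ("transform"/"filter"),
#'   n_in, n_out, reasons ("code=n;code=n").
#' @return TRUE invisibly; stops with an informative error otherwise.
#' @export
validateFunnel <- function(funnel) {
  stopifnot(all(c("stage", "type", "n_in", "n_out", "reasons") %in%
                names(funnel)))
  if (nrow(funnel) > 1L) {
    chained <- funnel$n_out[-nrow(funnel)] == funnel$n_in[-1L]
    if (!all(chained))
      .stopf("funnel does not chain between '%s' and '%s'",
             funnel$stage[which(!chained)[1L]],
             funnel$stage[which(!chained)[1L] + 1L])
  }
  flt <- funnel$type == "filter"
  if (any(funnel$n_out[flt] > funnel$n_in[flt]))
    .stopf("filtering stage '%s' emitted more records than it received",
           funnel$stage[flt & funnel$n_out > funnel$n_in][1L])
  for (i in which(flt)) {
    dropped <- funnel$n_in[i] - funnel$n_out[i]
    if (!nzchar(funnel$reasons[i])) {
      if (dropped != 0L)
        .stopf("stage '%s' dropped %d records without reasons",
               funnel$stage[i], dropped)
      next
    }
    counts <- as.integer(sub("^.*=", "",
                             strsplit(funnel$reasons[i], ";",
                                      fixed = TRUE)[[1L]]))
    if (sum(counts) != dropped)
      .stopf("stage '%s': reason counts (%d) do not account for dropped records (%d)",
             funnel$stage[i], sum(counts), dropped)
  }
  invisible(TRUE)
}

## collapse stacked annotation tables; duplicate keys with conflicting
## classifications become a single Conflicting record
#' @keywords internal
.collapseAnnotations <- function(tables) {
  ann <- do.call(rbind, tables)
  if (is.null(ann) || !nrow(ann)) return(ann)
  if (anyDuplicated(ann$key)) {
    keep <- !duplicated(ann$key)
    confl_keys <- unique(ann$key[ann$key %in% ann$key[duplicated(ann$key)]])
    confl <- vapply(confl_keys, function(k)
      length(unique(ann$classification[ann$key == k])) > 1L, TRUE)
    out <- ann[keep, , drop = FALSE]
    out$classification[out$key %in% confl_keys[confl]] <- "Conflicting"
    ## origin: somatic + germline evidence across sources means both
    both <- vapply(confl_keys, function(k) {
      o <- unique(ann$origin[ann$key == k])
      all(c("somatic", "germline") %in% o)
    }, TRUE)
    out$origin[out$key %in% confl_keys[both]] <- "both"
    ann <- out
  }
  rownames(ann) <- NULL
  ann
}

#' Run the full cohort prioritization pipeline
#'
#' Fixed stage order: consensus extraction, annotation matching and keyword
#' filtering, somatic/germline partition, frequency/rarity binning and GWAS
#' matching, occurrence ranking and zygosity-grade association, CNV overlap
#' with the bona fide filter, and (optionally) repeat-mosaicism profiling.
#' Each stage is also callable standalone through the exported functions.
#'
#' @param manifest VCF manifest data.frame (path, sample, caller).
#' @param reference \code{DNAStringSet} or named character vector, or a FASTA
#'   path.
#' @param tables named list of file paths: clinvar (and optionally cosmic,
#'   dbvar), gnomad, gip, gwas, cohort_sv, population_sv. Missing entries
#'   skip the stage.
#' @param metadata sample metadata data.frame or TSV path.
#' @param out_dir output directory for TSV/JSON artifacts (NULL = no files).
#' @param thresholds a \code{\link{qualityThresholds}}.
#' @param required_callers see \code{\link{consensusAcrossCallers}}.
#' @param keep_classes classification keyword filter (default the four
#'   keywords used for prioritization).
#' @param bona_fide a \code{\link{bonaFideConfig}}.
#' @param repeat_reads optional named list (sample -> read vector or
#'   FASTA/FASTQ path) for the repeat stage.
#' @param locus,mosaicism repeat-stage parameters.
#' @param extreme_threshold,common_threshold rarity boundaries.
#' @return list: consensus, variants (variant-level classified table),
#'   partition, rarity_report, gwas_hits, occurrence, zygosity, sv_pairs,
#'   bona_fide, snv_in_cnv, cnv_by_chromosome, repeat_profiles,
#'   mosaicism_summary, funnel, summary (the JSON-ready run summary).
#' @export
runCohortPipeline <- function(manifest, reference, tables = list(),
                              metadata = NULL, out_dir = NULL,
                              thresholds = qualityThresholds(),
                              required_callers = NULL,
                              keep_classes = c("Pathogenic",
                                               "Likely-pathogenic", "VUS",
                                               "Benign"),
                              bona_fide = bonaFideConfig(),
                              repeat_reads = NULL, locus = repeatLocus(),
                              mosaicism = mosaicismParams(),
                              extreme_threshold = 0.001,
                              common_threshold = 0.05) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- readReferenceFasta(reference)
  samples <- if (!is.null(metadata)) sampleMetadata(metadata) else NULL

  res <- extractConsensus(manifest, reference, thresholds, required_callers)
  cons <- res$consensus
  funnel <- res$funnel
  addStage <- function(stage, type, n_in, n_out, reasons = "") {
    rbind(funnel, data.frame(stage = stage, type = type,
                             n_in = as.integer(n_in),
                             n_out = as.integer(n_out),
                             reasons = reasons, stringsAsFactors = FALSE))
  }

  ## variant-level table + carriers
  variants <- cons[!duplicated(cons$key),
                   c("contig", "position", "ref", "alt", "key")]
  rownames(variants) <- NULL
  carriers <- data.frame(key = cons$key, sample = cons$sample,
                         stringsAsFactors = FALSE)
  funnel <- addStage("aggregate_variants", "transform", nrow(cons),
                     nrow(variants))

  out <- list(consensus = cons)
  classified <- NULL
  ann_tables <- list()
  for (src in c("clinvar", "cosmic", "dbvar"))
    if (!is.null(tables[[src]]))
      ann_tables[[src]] <- loadAnnotationTable(tables[[src]], src)
  if (length(ann_tables)) {
    ann <- .collapseAnnotations(ann_tables)
    matched <- matchVariants(variants, ann)
    kept <- filterByClassification(matched, keep_classes)
    n_unmatched <- sum(!matched$matched)
    n_class_drop <- nrow(matched) - n_unmatched - nrow(kept)
    funnel <- addStage("annotation_filter", "filter", nrow(matched),
                       nrow(kept),
                       .encodeReasons(c(unmatched = n_unmatched,
                                        classification_excluded =
                                          n_class_drop)))
    classified <- kept
    if (!is.null(samples)) {
      out$partition <- partitionSomaticGermline(kept, carriers, samples)
      classified <- out$partition$classified
    }
    out$variants <- classified
  }

  if (!is.null(tables$gnomad) || !is.null(tables$gip)) {
    gnomad <- if (!is.null(tables$gnomad))
      loadFrequencyTable(tables$gnomad) else NULL
    gip <- if (!is.null(tables$gip)) loadFrequencyTable(tables$gip) else NULL
    target <- if (!is.null(classified)) classified else variants
    freq <- joinFrequencies(target, gnomad, gip)
    freq$rarity <- classifyRarity(freq$gnomad_maf, extreme_threshold,
                                  common_threshold)
    out$variants <- freq
    out$rarity_report <- rarityReport(freq, freq$classification,
                                      extreme_threshold, common_threshold)
  }
  if (!is.null(tables$gwas)) {
    catalog <- loadGwasCatalog(tables$gwas)
    target <- if (!is.null(out$variants)) out$variants else variants
    out$gwas_hits <- matchGwas(target, catalog)
  }

  if (nrow(cons)) {
    pm <- presenceMatrix(cons, if (!is.null(samples)) samples$sample_id)
    out$occurrence <- rankOccurrence(pm)
    if (!is.null(samples)) {
      gts <- cons[!cons$discordant_gt & !is.na(cons$genotype),
                  c("key", "sample", "genotype")]
      strat_keys <- if (!is.null(classified))
        classified$key[!is.na(classified$classification) &
                       classified$classification %in%
                         c("Pathogenic", "Likely-pathogenic")]
      else unique(gts$key)
      gts <- gts[gts$key %in% strat_keys, , drop = FALSE]
      if (nrow(gts)) out$zygosity <- zygosityGradeAssociation(gts, samples)
    }
  }

  if (!is.null(tables$cohort_sv) && !is.null(tables$population_sv)) {
    cohort_sv <- readSvTable(tables$cohort_sv, "cohort")
    pop_sv <- readSvTable(tables$population_sv, "population")
    out$sv_pairs <- intersectSvs(cohort_sv, pop_sv, bona_fide)
    out$bona_fide <- bonaFideFilter(out$sv_pairs, cohort_sv, pop_sv,
                                    bona_fide)
    ## the CNV branch has its own record stream, hence its own funnel
    out$cnv_funnel <- data.frame(
      stage = "bona_fide_cnv", type = "filter",
      n_in = as.integer(nrow(cohort_sv)),
      n_out = as.integer(sum(out$bona_fide$bona_fide)),
      reasons = .encodeReasons(table(
        out$bona_fide$reason[!out$bona_fide$bona_fide])),
      stringsAsFactors = FALSE)
    validateFunnel(out$cnv_funnel)
    out$cnv_by_chromosome <- cnvChromosomeCounts(out$bona_fide)
    snv_sites <- variants[nchar(variants$ref) == 1L &
                          nchar(variants$alt) == 1L, , drop = FALSE]
    bona_ivs <- out$bona_fide[out$bona_fide$bona_fide, , drop = FALSE]
    out$snv_in_cnv <- snvInCnv(snv_sites, bona_ivs)
  }

  if (!is.null(repeat_reads)) {
    profiles <- lapply(names(repeat_reads), function(smp) {
      reads <- repeat_reads[[smp]]
      if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- readRepeatReads(reads)
      buildRepeatProfile(countRepeatUnits(reads, locus, sample = smp),
                         mosaicism)
    })
    out$repeat_profiles <- profiles
    out$mosaicism_summary <- cohortMosaicismSummary(profiles, samples)
  }

  out$funnel <- funnel
  validateFunnel(funnel)
  out$summary <- list(
    n_samples = length(unique(manifest$sample)),
    n_callers = length(unique(manifest$caller)),
    n_consensus_records = nrow(cons),
    n_consensus_variants = nrow(variants),
    rarity = out$rarity_report,
    n_bona_fide_cnv = if (!is.null(out$bona_fide))
      sum(out$bona_fide$bona_fide) else NULL,
    mosaicism = if (!is.null(out$mosaicism_summary))
      out$mosaicism_summary[c("n_samples", "n_callable", "n_mosaic",
                              "fraction_mosaic_callable")] else NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, file) {
      if (!is.null(df) && nrow(df))
        utils::write.table(df, file.path(out_dir, file), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    wt(cons, "consensus.tsv")
    if (!is.null(out$variants)) wt(out$variants, "classified_variants.tsv")
    if (!is.null(out$occurrence)) wt(out$occurrence, "occurrence.tsv")
    if (!is.null(out$zygosity)) wt(out$zygosity, "zygosity_grade.tsv")
    if (!is.null(out$sv_pairs)) wt(out$sv_pairs, "sv_overlap_pairs.tsv")
    if (!is.null(out$bona_fide)) wt(out$bona_fide, "bona_fide_cnv.tsv")
    if (!is.null(out$snv_in_cnv)) wt(out$snv_in_cnv, "snv_in_cnv.tsv")
    if (!is.null(out$cnv_by_chromosome))
      wt(out$cnv_by_chromosome, "cnv_by_chromosome.tsv")
    if (!is.null(out$repeat_profiles))
      wt(repeatProfileTable(out$repeat_profiles), "repeat_profiles.tsv")
    wt(funnel, "funnel.tsv")
    jsonlite::write_json(out$summary,
                         file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
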