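## Synthetic cohort generator: truth variants with the zygosity/grade and
## sharing structure of the study cohort, per-caller VCFs with controlled
## false-negative / false-positive / representation noise, annotation and
## frequency tables with decoys, and flank-anchored repeat-locus reads.
## Every emitter is fully determined by the configured seed.

#' @keywords internal
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

## candidate variant sites: fixed grid, 25 bp apart, away from contig ends.
## The spacing exceeds any allele length + left-alignment shift the generator
## can produce, so normalized truth keys never collide.
#' @keywords internal
.siteGrid <- function(contig_lengths) {
  do.call(rbind, lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    data.frame(contig = ctg, position = seq(30L, len - 60L, by = 25L),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate the truth set and sample metadata of a synthetic cohort
#'
#' Draws the cohort (tissue labels, Gleason patterns), germline truth
#' variants with sharing counts from the configured sharing distribution, and
#' somatic truth variants whose carriers are exclusively malignant samples
#' with the grade-linked zygosity rule: carriers with Gleason patterns 4+4 or
#' 4+3 are homozygous for the alternate allele, all other carriers are
#' heterozygous. Truth alleles are normalized, so truth keys are canonical.
#'
#' @param config a \code{\link{cohortConfig}}; the seed fully determines the
#'   output.
#' @return a \code{\linkS4class{SyntheticCohort}}.
#' @export
simulateTruth <- function(config = cohortConfig()) {
  methods::validObject(config)
  reference <- simulateReference(config@contig_lengths,
                                 seed = .deriveSeed(config@seed, 1L))
  refchars <- .referenceAsStrings(reference)
  set.seed(.deriveSeed(config@seed, 2L))

  ## ---- samples -----------------------------------------------------------
  n_unlab <- config@n_samples - config@n_malignant - config@n_bph
  tissue <- c(rep("malignant", config@n_malignant),
              rep("BPH", config@n_bph))
  material <- c(rep("FFPE", config@n_malignant + config@n_bph))
  labeled <- rep(TRUE, config@n_malignant + config@n_bph)
  if (n_unlab > 0 && config@unlabeled_policy == "malignant") {
    tissue <- c(tissue, rep("malignant", n_unlab))
    material <- c(material, rep("fresh_frozen", n_unlab))
    labeled <- c(labeled, rep(FALSE, n_unlab))
  }
  n_eff <- length(tissue)
  ids <- sprintf("S%02d", seq_len(n_eff))
  pat <- character(n_eff)
  mal <- tissue == "malignant"
  pat[mal] <- .sampleVec(names(config@gleason_distribution), sum(mal),
                         replace = TRUE, prob = config@gleason_distribution)
  pat[!mal] <- .sampleVec(names(config@bph_gleason_distribution), sum(!mal),
                          replace = TRUE,
                          prob = config@bph_gleason_distribution)
  pp <- strsplit(pat, "+", fixed = TRUE)
  samples <- sampleMetadata(data.frame(
    sample_id = ids, tissue = tissue,
    gleason_primary = as.integer(vapply(pp, `[`, "", 1L)),
    gleason_secondary = as.integer(vapply(pp, `[`, "", 2L)),
    material = material, labeled = labeled, stringsAsFactors = FALSE))

  ## ---- truth variant sites and alleles ------------------------------------
  grid <- .siteGrid(config@contig_lengths)
  n_total <- config@n_germline_truth + config@n_somatic_truth
  if (n_total > nrow(grid))
    .stopf("%d truth variants requested but only %d candidate sites exist; enlarge contig_lengths",
           n_total, nrow(grid))
  take <- sort(sample.int(nrow(grid), n_total))
  sites <- grid[take, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  n <- nrow(sites)
  ref <- substring(refchars[sites$contig], sites$position, sites$position)
  alt <- vapply(ref, function(b) .sampleVec(setdiff(bases, b), 1L), "")
  is_indel <- stats::runif(n) < config@indel_fraction
  if (any(is_indel)) {
    for (i in which(is_indel)) {
      l <- sample.int(5L, 1L)
      if (stats::runif(1) < 0.5) {  # deletion: anchor + deleted bases
        ref[i] <- substring(refchars[sites$contig[i]], sites$position[i],
                            sites$position[i] + l)
        alt[i] <- substring(ref[i], 1L, 1L)
      } else {                      # insertion after the anchor base
        ins <- paste(.sampleVec(bases, l, replace = TRUE), collapse = "")
        alt[i] <- paste0(ref[i], ins)
      }
    }
  }
  truth <- data.frame(contig = sites$contig, position = sites$position,
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
  truth <- normalizeVariants(truth, reference)
  if (anyDuplicated(truth$key))
    .stopf("internal: truth keys collided after normalization")
  truth$origin <- .sampleVec(c(rep("germline", config@n_germline_truth),
                               rep("somatic", config@n_somatic_truth)), n)

  ## ---- carriers and genotypes ---------------------------------------------
  mal_ids <- samples$sample_id[samples$tissue == "malignant"]
  high_ids <- samples$sample_id[samples$grade_group == "high"]
  geno <- vector("list", n)
  n_carriers <- integer(n)
  share_k <- suppressWarnings(as.integer(names(config@sharing_distribution)))
  for (i in seq_len(n)) {
    if (truth$origin[i] == "germline") {
      k <- min(.sampleVec(share_k, 1L, prob = config@sharing_distribution),
               n_eff)
      car <- .sampleVec(samples$sample_id, k)
      gt <- ifelse(stats::runif(k) < config@germline_hom_fraction,
                   "hom_alt", "het")
    } else {
      lo <- min(config@somatic_carrier_range[1L], length(mal_ids))
      hi <- min(config@somatic_carrier_range[2L], length(mal_ids))
      k <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      car <- .sampleVec(mal_ids, k)
      gt <- ifelse(car %in% high_ids, "hom_alt", "het")
    }
    geno[[i]] <- data.frame(key = truth$key[i], sample_id = car,
                            genotype = gt, stringsAsFactors = FALSE)
    n_carriers[i] <- k
  }
  genotypes <- do.call(rbind, geno)
  truth$n_carriers <- n_carriers

  ## ---- planted annotations and frequencies --------------------------------
  som <- truth$origin == "somatic"
  cls_pool <- c("Pathogenic", "Likely-pathogenic", "VUS", "Benign",
                "Likely-benign", "Conflicting")
  truth$classification <- NA_character_
  truth$classification[som] <- .sampleVec(
    cls_pool, sum(som), replace = TRUE,
    prob = c(0.30, 0.15, 0.30, 0.10, 0.10, 0.05))
  germ <- which(!som)
  has_cls <- germ[stats::runif(length(germ)) < 0.5]
  truth$classification[has_cls] <- .sampleVec(
    c("Pathogenic", "Likely-pathogenic", "VUS", "Benign", "Likely-benign"),
    length(has_cls), replace = TRUE, prob = c(0.15, 0.1, 0.35, 0.3, 0.1))
  truth$gnomad_maf <- ifelse(stats::runif(n) < 0.4, NA_real_,
                             10^stats::runif(n, -7, log10(0.5)))
  truth$gip_aaf <- ifelse(stats::runif(n) < 0.5, NA_real_,
                          10^stats::runif(n, -6, log10(0.6)))
  rownames(truth) <- NULL
  new("SyntheticCohort", truth = truth, genotypes = genotypes,
      samples = samples, reference = reference, config = config)
}

#' Default caller profiles emulating four distinct callers
#'
#' Four callers with mildly different false-negative/false-positive behavior
#' and representation dialects (one right-shifts indels, one merges het SNVs
#' into multiallelic records). Per-caller error rates are free parameters of
#' the generator, not estimates.
#'
#' @return named list of four \code{\link{callerProfile}} objects.
#' @export
defaultCallerProfiles <- function() {
  list(varscan = callerProfile("varscan", fn_rate = 0.03, fp_rate = 3,
                               representation_style = "minimal",
                               nonpass_fraction = 0.03),
       bcftools = callerProfile("bcftools", fn_rate = 0.05, fp_rate = 2,
                                representation_style = "right_shifted",
                                nonpass_fraction = 0.02),
       freebayes = callerProfile("freebayes", fn_rate = 0.04, fp_rate = 4,
                                 representation_style = "multiallelic_merged",
                                 nonpass_fraction = 0.05),
       vt = callerProfile("vt", fn_rate = 0.02, fp_rate = 1,
                          representation_style = "minimal",
                          nonpass_fraction = 0.01))
}

#' Noise-free caller profiles
#'
#' Four callers with fn = fp = 0, minimal representation, all-PASS, and
#' depth/quality models kept above the default filter thresholds, so the
#' downstream consensus must equal the truth set exactly (the end-to-end
#' closure oracle).
#'
#' @return named list of four \code{CallerProfile} objects.
#' @export
noiseFreeProfiles <- function() {
  mk <- function(id) callerProfile(id, fn_rate = 0, fp_rate = 0,
                                   representation_style = "minimal",
                                   depth_mean = 110, depth_dispersion = 5,
                                   depth_min = 30, gq_mean = 90, gq_sd = 3,
                                   nonpass_fraction = 0)
  list(varscan = mk("varscan"), bcftools = mk("bcftools"),
       freebayes = mk("freebayes"), vt = mk("vt"))
}

## right-most equivalent representation of a normalized biallelic variant
#' @keywords internal
.rightShift <- function(seqchar, pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) return(list(position = pos, ref = ref, alt = alt))
  len <- nchar(seqchar)
  if (nr > na) {                       # deletion: ref = anchor + X
    k <- nr - 1L
    while (pos + k + 1L <= len &&
           substr(seqchar, pos + 1L, pos + 1L) ==
           substr(seqchar, pos + k + 1L, pos + k + 1L))
      pos <- pos + 1L
    list(position = pos, ref = substr(seqchar, pos, pos + k),
         alt = substr(seqchar, pos, pos))
  } else {                             # insertion of X after the anchor
    X <- substr(alt, 2L, na)
    while (pos + 1L <= len &&
           substr(X, 1L, 1L) == substr(seqchar, pos + 1L, pos + 1L)) {
      X <- paste0(substr(X, 2L, nchar(X)), substr(X, 1L, 1L))
      pos <- pos + 1L
    }
    anchor <- substr(seqchar, pos, pos)
    list(position = pos, ref = anchor, alt = paste0(anchor, X))
  }
}

#' @keywords internal
.vcfHeader <- function(contig_lengths, sample) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            contig_lengths),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=LowQual,Description=\"Low quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
}

#' Emit per-sample per-caller VCFs with controlled noise
#'
#' For each sample and caller profile: carried truth variants are dropped
#' with probability \code{fn_rate}; Poisson(\code{fp_rate}) false calls are
#' added at sites disjoint from the truth; records are rendered in the
#' caller's representation style; GT/DP/GQ/AD are drawn from the profile's
#' depth and quality models (het allele fraction uniform in 0.3-0.7, hom in
#' 0.92-1); FILTER is PASS except a \code{nonpass_fraction} flagged LowQual.
#' Files are named \code{<sample>.<caller>.vcf}.
#'
#' @param cohort a \code{SyntheticCohort}.
#' @param profiles list of \code{\link{callerProfile}} objects with distinct
#'   ids (default four noise-free callers).
#' @param dir output directory (created if needed).
#' @param seed integer; defaults to a value derived from the cohort seed.
#' @return manifest data.frame (sample, caller, path), invisibly usable with
#'   \code{\link{extractConsensus}}.
#' @export
emitCallerVcfs <- function(cohort, profiles = noiseFreeProfiles(), dir,
                           seed = NULL) {
  stopifnot(is(cohort, "SyntheticCohort"))
  ids <- vapply(profiles, function(p) p@caller_id, "")
  if (anyDuplicated(ids)) .stopf("caller profiles must have distinct ids")
  refchars <- .referenceAsStrings(cohort@reference)
  clen <- stats::setNames(nchar(refchars), names(refchars))
  truth <- cohort@truth
  outside <- !truth$contig %in% names(clen) |
    truth$position + nchar(truth$ref) - 1L > clen[truth$contig]
  if (any(outside)) {
    i <- which(outside)[1L]
    .stopf("truth position outside reference: %s:%d", truth$contig[i],
           truth$position[i])
  }
  if (is.null(seed)) seed <- .deriveSeed(cohort@config@seed, 3L)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  grid <- .siteGrid(cohort@config@contig_lengths)
  fp_pool <- grid[!paste(grid$contig, grid$position) %in%
                  paste(truth$contig, truth$position), , drop = FALSE]
  gstack <- cohort@genotypes
  bases <- c("A", "C", "G", "T")
  manifest <- list()
  for (smp in cohort@samples$sample_id) {
    gsmp <- gstack[gstack$sample_id == smp, , drop = FALSE]
    carried <- truth[match(gsmp$key, truth$key), , drop = FALSE]
    carried$genotype <- gsmp$genotype
    for (prof in profiles) {
      keep <- stats::runif(nrow(carried)) >= prof@fn_rate
      rec <- carried[keep, c("contig", "position", "ref", "alt", "genotype")]
      n_fp <- stats::rpois(1L, prof@fp_rate)
      if (n_fp > 0 && nrow(fp_pool)) {
        fp_sites <- fp_pool[sample.int(nrow(fp_pool), n_fp), , drop = FALSE]
        fp_ref <- substring(refchars[fp_sites$contig], fp_sites$position,
                            fp_sites$position)
        fp_alt <- vapply(fp_ref, function(b) .sampleVec(setdiff(bases, b),
                                                        1L), "")
        rec <- rbind(rec, data.frame(contig = fp_sites$contig,
                                     position = fp_sites$position,
                                     ref = fp_ref, alt = fp_alt,
                                     genotype = "het",
                                     stringsAsFactors = FALSE))
      }
      m <- nrow(rec)
      dp <- pmax(prof@depth_min,
                 stats::rnbinom(m, size = prof@depth_dispersion,
                                mu = prof@depth_mean))
      af <- ifelse(rec$genotype == "het", stats::runif(m, 0.3, 0.7),
                   stats::runif(m, 0.92, 1.0))
      ad_alt <- round(dp * af)
      ad_ref <- dp - ad_alt
      gq <- pmin(99, pmax(0, round(stats::rnorm(m, prof@gq_mean,
                                                prof@gq_sd))))
      filt <- ifelse(stats::runif(m) < prof@nonpass_fraction, "LowQual",
                     "PASS")
      gt <- ifelse(rec$genotype == "hom_alt", "1/1", "0/1")
      alt_field <- rec$alt
      ad_field <- paste(ad_ref, ad_alt, sep = ",")
      if (prof@representation_style == "right_shifted") {
        indel <- nchar(rec$ref) != nchar(rec$alt)
        for (i in which(indel)) {
          rs <- .rightShift(refchars[[rec$contig[i]]], rec$position[i],
                            rec$ref[i], rec$alt[i])
          rec$position[i] <- rs$position
          rec$ref[i] <- rs$ref
          alt_field[i] <- rs$alt
        }
      } else if (prof@representation_style == "multiallelic_merged") {
        mrg <- rec$genotype == "het" & nchar(rec$ref) == 1L &
          nchar(rec$alt) == 1L
        if (any(mrg)) {
          decoy <- vapply(which(mrg), function(i)
            .sampleVec(setdiff(bases, c(rec$ref[i], rec$alt[i])), 1L), "")
          alt_field[mrg] <- paste(rec$alt[mrg], decoy, sep = ",")
          ad_field[mrg] <- paste(ad_ref[mrg], ad_alt[mrg], 1L, sep = ",")
        }
      }
      ord <- order(rec$contig, rec$position, alt_field)
      body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT:DP:GQ:AD\t%s:%d:%d:%s",
                      rec$contig[ord], rec$position[ord], rec$ref[ord],
                      alt_field[ord], filt[ord], gt[ord], dp[ord], gq[ord],
                      ad_field[ord])
      path <- file.path(dir, sprintf("%s.%s.vcf", smp, prof@caller_id))
      writeLines(c(.vcfHeader(clen, smp), body), path)
      manifest[[length(manifest) + 1L]] <-
        data.frame(sample = smp, caller = prof@caller_id, path = path,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, manifest)
}

#' Write the sample metadata TSV
#' @param cohort a \code{SyntheticCohort}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeSampleMetadata <- function(cohort, path) {
  utils::write.table(cohort@samples[, c("sample_id", "tissue",
                                        "gleason_primary",
                                        "gleason_secondary")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit annotation, frequency, GWAS and SV tables for a synthetic cohort
#'
#' Planted classifications and frequencies appear under the exact key of each
#' truth variant; a configurable fraction of decoy rows with non-matching
#' keys is added to every table. Truth variants with a not-reported planted
#' frequency have no row in the corresponding frequency table.
#'
#' @param cohort a \code{SyntheticCohort}.
#' @param dir output directory.
#' @param decoy_fraction decoy rows as a fraction of true rows (default 0.1).
#' @param n_cohort_sv,n_population_sv interval counts for the SV tables.
#' @param seed integer; defaults to a value derived from the cohort seed.
#' @return named list of file paths.
#' @export
emitAnnotationTables <- function(cohort, dir, decoy_fraction = 0.1,
                                 n_cohort_sv = 60L, n_population_sv = 120L,
                                 seed = NULL) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (is.null(seed)) seed <- .deriveSeed(cohort@config@seed, 4L)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- cohort@truth
  grid <- .siteGrid(cohort@config@contig_lengths)
  decoy_pool <- grid[!paste(grid$contig, grid$position) %in%
                     paste(truth$contig, truth$position), , drop = FALSE]
  refchars <- .referenceAsStrings(cohort@reference)
  bases <- c("A", "C", "G", "T")
  gene_pool <- c("APC", "BRAF", "ATM", "TP53", "SMAD4", "CHEK2", "PMS2",
                 "BRCA1", "BRCA2", "PTEN", "AR", "FOXA1", "MYC")
  mkDecoys <- function(k) {
    if (k <= 0 || !nrow(decoy_pool)) return(NULL)
    s <- decoy_pool[sample.int(nrow(decoy_pool), min(k, nrow(decoy_pool))), ,
                    drop = FALSE]
    rf <- substring(refchars[s$contig], s$position, s$position)
    data.frame(contig = s$contig, position = s$position, ref = rf,
               alt = vapply(rf, function(b) .sampleVec(setdiff(bases, b),
                                                       1L), ""),
               stringsAsFactors = FALSE)
  }
  wt <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  fmtNum <- function(x) ifelse(is.na(x), "NR", format(x, scientific = TRUE,
                                                      digits = 6))

  annTable <- function(rows) {
    data.frame(contig = rows$contig, position = rows$position,
               ref = rows$ref, alt = rows$alt,
               rsid = sprintf("rs%07d",
                              sample.int(9999999L, nrow(rows))),
               gene = .sampleVec(gene_pool, nrow(rows), replace = TRUE),
               classification = rows$classification, origin = rows$origin,
               stringsAsFactors = FALSE)
  }
  cls_rows <- truth[!is.na(truth$classification), , drop = FALSE]
  clinvar <- annTable(cls_rows)
  dec <- mkDecoys(round(decoy_fraction * nrow(clinvar)))
  if (!is.null(dec)) {
    dec$classification <- .sampleVec(c("Pathogenic", "Benign", "VUS"),
                                     nrow(dec), replace = TRUE)
    dec$origin <- .sampleVec(c("germline", "somatic"), nrow(dec),
                             replace = TRUE)
    clinvar <- rbind(clinvar, annTable(dec))
  }
  paths <- list(clinvar = wt(clinvar, "clinvar.tsv"))

  cos_rows <- truth[truth$origin == "somatic" &
                    !is.na(truth$classification), , drop = FALSE]
  paths$cosmic <- wt(annTable(cos_rows), "cosmic.tsv")

  freqTable <- function(col) {
    rows <- truth[!is.na(truth[[col]]), , drop = FALSE]
    df <- data.frame(contig = rows$contig, position = rows$position,
                     ref = rows$ref, alt = rows$alt,
                     frequency = fmtNum(rows[[col]]),
                     stringsAsFactors = FALSE)
    dec <- mkDecoys(round(decoy_fraction * nrow(df)))
    if (!is.null(dec)) {
      dec$frequency <- fmtNum(10^stats::runif(nrow(dec), -6, -0.5))
      df <- rbind(df, dec)
    }
    df
  }
  paths$gnomad <- wt(freqTable("gnomad_maf"), "gnomad.tsv")
  paths$gip <- wt(freqTable("gip_aaf"), "gip.tsv")

  gw_rows <- truth[truth$origin == "germline" &
                   !is.na(truth$classification) &
                   truth$classification == "Pathogenic", , drop = FALSE]
  gwas <- data.frame(contig = gw_rows$contig, position = gw_rows$position,
                     ref = gw_rows$ref, alt = gw_rows$alt,
                     p_value = signif(stats::runif(nrow(gw_rows), 1e-8,
                                                   0.05), 3),
                     trait = "prostate_carcinoma", stringsAsFactors = FALSE)
  dec <- mkDecoys(round(decoy_fraction * max(nrow(gwas), 10L)))
  if (!is.null(dec)) {
    dec$p_value <- signif(stats::runif(nrow(dec), 1e-8, 0.05), 3)
    dec$trait <- "prostate_carcinoma"
    gwas <- rbind(gwas, dec)
  }
  paths$gwas <- wt(gwas, "gwas.tsv")

  mkSv <- function(k, population) {
    ctg <- .sampleVec(names(cohort@config@contig_lengths), k, replace = TRUE)
    len <- cohort@config@contig_lengths[ctg]
    start <- floor(stats::runif(k, 0, pmax(1, len - 20000)))
    width <- floor(stats::runif(k, 500, 20000))
    df <- data.frame(contig = ctg, start = as.integer(start),
                     end = as.integer(pmin(start + width, len)),
                     sv_type = .sampleVec(c("DEL", "DUP", "INS", "INV"), k,
                                          replace = TRUE),
                     stringsAsFactors = FALSE)
    if (population) {
      an <- rep(10000L, k)
      maf <- 10^stats::runif(k, -5, -0.5)
      nr <- stats::runif(k) < 0.15
      df$pop_maf <- ifelse(nr, "NR", format(maf, digits = 4))
      df$allele_count <- ifelse(nr, "NR", as.character(round(maf * an)))
      df$allele_number <- ifelse(nr, "NR", as.character(an))
    } else {
      df$pop_maf <- "NR"; df$allele_count <- "NR"; df$allele_number <- "NR"
    }
    df
  }
  paths$cohort_sv <- wt(mkSv(n_cohort_sv, FALSE), "cohort_sv.tsv")
  paths$population_sv <- wt(mkSv(n_population_sv, TRUE), "population_sv.tsv")
  paths$metadata <- writeSampleMetadata(cohort,
                                        file.path(dir,
                                                  "sample_metadata.tsv"))
  paths
}

#' Simulate reads over a flank-anchored repeat locus
#'
#' Each spanning read is left flank + unit x L + right flank, with L drawn
#' from the allele mixture. Substitution errors are injected per base at
#' \code{error_rate}; a fraction of reads is truncated before the right flank
#' (non-spanning).
#'
#' @param allele_lengths integer vector of repeat counts (>= 1).
#' @param fractions mixture fractions summing to 1.
#' @param n_reads number of reads (0 gives an empty set, no error).
#' @param locus a \code{\link{repeatLocus}}.
#' @param error_rate per-base substitution probability.
#' @param nonspanning_fraction fraction of reads truncated before the right
#'   flank.
#' @param seed integer seed.
#' @return named character vector of read sequences.
#' @export
simulateRepeatReads <- function(allele_lengths, fractions = NULL,
                                n_reads = 50L, locus = repeatLocus(),
                                error_rate = 0, nonspanning_fraction = 0,
                                seed = 1L) {
  stopifnot(is(locus, "RepeatLocus"), all(allele_lengths >= 1L))
  if (is.null(fractions))
    fractions <- rep(1 / length(allele_lengths), length(allele_lengths))
  if (abs(sum(fractions) - 1) > 1e-9)
    .stopf("mixture fractions must sum to 1")
  set.seed(seed)
  if (n_reads == 0L) return(stats::setNames(character(), character()))
  L <- .sampleVec(allele_lengths, n_reads, replace = TRUE, prob = fractions)
  reads <- paste0(locus@left_flank, strrep(locus@unit, L),
                  locus@right_flank)
  trunc <- stats::runif(n_reads) < nonspanning_fraction
  if (any(trunc)) {
    keep_len <- nchar(locus@left_flank) + nchar(locus@unit) * L[trunc]
    reads[trunc] <- substr(reads[trunc], 1L, keep_len)
  }
  if (error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n_reads)) {
      n_err <- stats::rbinom(1L, nchar(reads[i]), error_rate)
      if (n_err > 0) {
        at <- sample.int(nchar(reads[i]), n_err)
        for (p in at)
          substr(reads[i], p, p) <-
            .sampleVec(setdiff(bases, substr(reads[i], p, p)), 1L)
      }
    }
  }
  stats::setNames(reads, sprintf("read_%04d", seq_len(n_reads)))
}

#' Write reads as FASTQ
#' @param reads named character vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRepeatFastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
  writeLines(as.vector(rbind(paste0("@", names(reads)), reads, "+", qual)),
             path)
  invisible(path)
}

#' Read repeat-locus reads from FASTA/FASTQ
#' @param path file; format inferred from the extension.
#' @return named character vector of read sequences.
#' @export
readRepeatReads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), names(x))
}

#' Simulate a cohort of repeat-locus read sets with planted mosaicism
#'
#' Each sample is mosaic with probability \code{mosaic_fraction} (two
#' distinct allele lengths with mixture fractions in 0.35-0.65), otherwise
#' carries a single allele. Allele lengths are drawn uniformly from
#' \code{allele_range}.
#'
#' @param n_samples number of samples.
#' @param mosaic_fraction planted mosaic probability (default 0.36).
#' @param allele_range integer vector of candidate repeat counts.
#' @param n_reads reads per sample.
#' @param locus a \code{\link{repeatLocus}}.
#' @param error_rate,nonspanning_fraction passed to
#'   \code{\link{simulateRepeatReads}}.
#' @param seed integer seed.
#' @return list with \code{truth} (data.frame sample, alleles, mosaic) and
#'   \code{reads} (named list of read vectors).
#' @export
simulateRepeatCohort <- function(n_samples = 49L, mosaic_fraction = 0.36,
                                 allele_range = 10:30, n_reads = 60L,
                                 locus = repeatLocus(), error_rate = 0,
                                 nonspanning_fraction = 0, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_samples))
  mosaic <- stats::runif(n_samples) < mosaic_fraction
  alleles <- lapply(seq_len(n_samples), function(i) {
    if (mosaic[i]) sort(.sampleVec(allele_range, 2L)) else
      .sampleVec(allele_range, 1L)
  })
  fracs <- lapply(seq_len(n_samples), function(i) {
    if (mosaic[i]) { f <- stats::runif(1, 0.35, 0.65); c(f, 1 - f) } else 1
  })
  read_seeds <- .deriveSeed(seed, 100L + seq_len(n_samples))
  reads <- lapply(seq_len(n_samples), function(i)
    simulateRepeatReads(alleles[[i]], fracs[[i]], n_reads, locus,
                        error_rate, nonspanning_fraction,
                        seed = read_seeds[i]))
  names(reads) <- ids
  list(truth = data.frame(sample = ids,
                          alleles = vapply(alleles, paste, "",
                                           collapse = ","),
                          mosaic = mosaic, stringsAsFactors = FALSE),
       reads = reads)
}
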