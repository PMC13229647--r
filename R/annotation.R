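## Clinical annotation matching: position + alternate-allele joins against
## ClinVar/COSMIC/dbVar-like tables, keyword filtering, somatic/germline
## partition. rsIDs are never used as join keys.

#' Closed classification vocabulary and synonym map
#'
#' Raw classification strings are mapped (case-insensitively) onto the closed
#' vocabulary {Pathogenic, Likely-pathogenic, Likely-benign, Benign, VUS,
#' Conflicting}. "Variant of Uncertain Significance" and "VUS" are synonyms;
#' "Conflicting pathogenicity" and ClinVar's longer conflicting phrasings map
#' to Conflicting.
#'
#' @return named character vector: names are lower-cased raw strings, values
#'   canonical classes.
#' @export
classificationVocabulary <- function() {
  c("pathogenic" = "Pathogenic",
    "likely pathogenic" = "Likely-pathogenic",
    "likely-pathogenic" = "Likely-pathogenic",
    "likely_pathogenic" = "Likely-pathogenic",
    "likely benign" = "Likely-benign",
    "likely-benign" = "Likely-benign",
    "likely_benign" = "Likely-benign",
    "benign" = "Benign",
    "vus" = "VUS",
    "variant of uncertain significance" = "VUS",
    "uncertain significance" = "VUS",
    "uncertain_significance" = "VUS",
    "conflicting" = "Conflicting",
    "conflicting pathogenicity" = "Conflicting",
    "conflicting interpretations of pathogenicity" = "Conflicting",
    "conflicting classifications of pathogenicity" = "Conflicting")
}

#' @keywords internal
.mapClassification <- function(x) {
  vocab <- classificationVocabulary()
  unname(vocab[tolower(trimws(x))])
}

#' Load a clinical annotation table
#'
#' Reads a TSV with header contig, position, ref, alt, rsid, gene,
#' classification, origin. Classification strings are mapped through
#' \code{\link{classificationVocabulary}}; rows with unknown strings are
#' dropped with a warning naming the row numbers. Duplicate keys with
#' conflicting classifications are collapsed to a single record classified
#' \code{Conflicting}.
#'
#' @param path TSV file.
#' @param source one of "clinvar", "cosmic", "dbvar" (recorded per record;
#'   a missing origin column defaults to "somatic" for cosmic and "unknown"
#'   otherwise).
#' @return data.frame of annotation records with a \code{key} column.
#' @export
loadAnnotationTable <- function(path, source = c("clinvar", "cosmic",
                                                 "dbvar")) {
  source <- match.arg(source)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  required <- c("contig", "position", "ref", "alt", "classification")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    .stopf("annotation table %s lacks required column(s): %s", path,
           paste(missing_cols, collapse = ", "))
  if (!nrow(tab)) {
    return(data.frame(contig = character(), position = integer(),
                      ref = character(), alt = character(),
                      rsid = character(), gene = character(),
                      classification = character(), origin = character(),
                      source = character(), key = character(),
                      stringsAsFactors = FALSE))
  }
  tab$position <- as.integer(tab$position)
  if (is.null(tab$rsid)) tab$rsid <- NA_character_
  if (is.null(tab$gene)) tab$gene <- NA_character_
  if (is.null(tab$origin))
    tab$origin <- if (source == "cosmic") "somatic" else "unknown"
  tab$origin[!tab$origin %in% c("somatic", "germline", "both", "unknown")] <-
    "unknown"
  mapped <- .mapClassification(tab$classification)
  bad <- is.na(mapped)
  if (any(bad)) {
    .warnf("dropping %d row(s) with unknown classification (rows %s)",
           sum(bad), paste(utils::head(which(bad), 10L), collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
    mapped <- mapped[!bad]
  }
  tab$classification <- mapped
  tab$source <- source
  tab$key <- variantKey(tab$contig, tab$position, tab$ref, tab$alt)
  ## collapse duplicate keys; conflicting classifications become Conflicting
  if (anyDuplicated(tab$key)) {
    split_idx <- split(seq_len(nrow(tab)), tab$key)
    keep <- vapply(split_idx, `[`, 1L, 1L)
    out <- tab[keep, , drop = FALSE]
    confl <- vapply(split_idx, function(ix)
      length(unique(tab$classification[ix])) > 1L, TRUE)
    out$classification[confl[match(out$key, names(split_idx))]] <-
      "Conflicting"
    tab <- out[order(keep), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[, c("contig", "position", "ref", "alt", "rsid", "gene",
          "classification", "origin", "source", "key")]
}

#' Match variants against annotation records
#'
#' Exact (contig, position, alt) match with a reference-allele consistency
#' check: a position+alt match whose ref disagrees raises a
#' data-inconsistency warning and is not matched. Unmatched variants are
#' carried forward with NA annotation columns.
#'
#' @param variants data.frame with contig, position, ref, alt (consensus
#'   variants or any normalized variant table).
#' @param annotations data.frame from \code{\link{loadAnnotationTable}}.
#' @return \code{variants} with added columns rsid, gene, classification,
#'   origin, ann_source and \code{matched} (logical).
#' @export
matchVariants <- function(variants, annotations) {
  vkey3 <- paste(variants$contig, variants$position, variants$alt, sep = ":")
  akey3 <- paste(annotations$contig, annotations$position, annotations$alt,
                 sep = ":")
  idx <- match(vkey3, akey3)
  hit <- !is.na(idx)
  ref_clash <- hit & variants$ref != annotations$ref[idx]
  if (any(ref_clash)) {
    i <- which(ref_clash)[1L]
    .warnf("reference disagreement at %s:%d (variant ref '%s', annotation ref '%s'); %d match(es) discarded",
           variants$contig[i], variants$position[i], variants$ref[i],
           annotations$ref[idx[i]], sum(ref_clash))
    idx[ref_clash] <- NA_integer_
    hit <- !is.na(idx)
  }
  variants$rsid <- annotations$rsid[idx]
  variants$gene <- annotations$gene[idx]
  variants$classification <- annotations$classification[idx]
  variants$origin <- annotations$origin[idx]
  variants$ann_source <- annotations$source[idx]
  variants$matched <- hit
  variants
}

#' Filter matched variants by clinical classification
#'
#' @param classified data.frame with a \code{classification} column.
#' @param keep character vector of classes to retain (canonical vocabulary
#'   values); must be non-empty.
#' @return the retained subset; per-class counts are attached as
#'   \code{attr(, "class_counts")}.
#' @export
filterByClassification <- function(classified, keep) {
  if (!length(keep)) .stopf("'keep' must name at least one classification")
  unknown <- setdiff(keep, unique(classificationVocabulary()))
  if (length(unknown))
    .stopf("unknown classification(s) in 'keep': %s",
           paste(unknown, collapse = ", "))
  out <- classified[!is.na(classified$classification) &
                    classified$classification %in% keep, , drop = FALSE]
  counts <- table(factor(out$classification,
                         levels = sort(unique(classificationVocabulary()))))
  attr(out, "class_counts") <- counts
  out
}

#' Partition classified variants into somatic / germline / unresolved
#'
#' Applies the cohort rule: a variant is called somatic iff its annotation
#' origin supports somatic (origin somatic or both) AND no BPH sample carries
#' it; a somatic-annotated variant seen in a BPH sample is demoted to
#' unresolved. A variant is germline when its annotation origin is germline,
#' or when a BPH sample carries it and the annotation does not claim a purely
#' somatic origin.
#'
#' @param classified variant-level data.frame with \code{key} and
#'   \code{origin} columns (from \code{\link{matchVariants}}).
#' @param carriers data.frame with columns key, sample: one row per carrier.
#' @param samples sample metadata (see \code{\link{sampleMetadata}}) with
#'   sample_id and tissue.
#' @return list with elements \code{somatic}, \code{germline},
#'   \code{unresolved} (row subsets) and \code{classified} (the input with a
#'   \code{cohort_origin_call} column and \code{n_carriers},
#'   \code{n_bph_carriers} counts). The three subsets are disjoint and
#'   exhaustive.
#' @export
partitionSomaticGermline <- function(classified, carriers, samples) {
  bph_ids <- samples$sample_id[samples$tissue == "BPH"]
  n_car <- vapply(classified$key, function(k)
    sum(carriers$key == k), 1L)
  n_bph <- vapply(classified$key, function(k)
    sum(carriers$key == k & carriers$sample %in% bph_ids), 1L)
  origin <- classified$origin
  origin[is.na(origin)] <- "unknown"
  call <- rep("unresolved", nrow(classified))
  somatic_origin <- origin %in% c("somatic", "both")
  call[somatic_origin & n_bph == 0L] <- "somatic"
  call[origin == "germline"] <- "germline"
  call[n_bph > 0L & origin %in% c("both", "unknown", "germline")] <- "germline"
  ## somatic-only annotation contradicted by a BPH carrier stays unresolved
  classified$cohort_origin_call <- call
  classified$n_carriers <- n_car
  classified$n_bph_carriers <- n_bph
  list(somatic = classified[call == "somatic", , drop = FALSE],
       germline = classified[call == "germline", , drop = FALSE],
       unresolved = classified[call == "unresolved", , drop = FALSE],
       classified = classified)
}
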