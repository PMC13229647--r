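## Packaged worked-example fixture: the 12 consensus somatic variants of the
## study cohort with their ClinVar classifications, gnomAD MAFs and
## GenomeIndia AAFs. One row (rs1800371) carries a composite alt ("C/A") and
## a composite GIP value in the source table; it is preserved verbatim as a
## single record, and its frequencies parse as not-reported.

#' The packaged 12-variant consensus somatic fixture
#'
#' @return data.frame, one row per variant: contig, position, rsid, gene,
#'   ref, alt, classification (raw string), gnomad_maf, gip_aaf (raw strings,
#'   "NR" = not reported).
#' @export
consensusSomaticFixture <- function() {
  path <- system.file("extdata", "consensus_somatic_12.tsv",
                      package = "ConsensusVariants", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character")
}

#' @rdname consensusSomaticFixture
#' @details \code{fixtureAnnotationRecords} presents the fixture as
#'   annotation records (classification mapped onto the closed vocabulary,
#'   origin "somatic"), the shape \code{\link{matchVariants}} consumes.
#' @export
fixtureAnnotationRecords <- function() {
  tab <- consensusSomaticFixture()
  data.frame(contig = tab$contig, position = as.integer(tab$position),
             ref = tab$ref, alt = tab$alt, rsid = tab$rsid, gene = tab$gene,
             classification = .mapClassification(tab$classification),
             origin = "somatic", source = "clinvar",
             key = variantKey(tab$contig, tab$position, tab$ref, tab$alt),
             stringsAsFactors = FALSE)
}

#' @rdname consensusSomaticFixture
#' @details \code{fixtureFrequencyTables} presents the fixture's gnomAD MAF
#'   and GenomeIndia AAF columns as frequency tables ("NR" and composite
#'   values parse as not-reported).
#' @export
fixtureFrequencyTables <- function() {
  tab <- consensusSomaticFixture()
  parse_freq <- function(x) {
    out <- suppressWarnings(as.numeric(x))
    out
  }
  base <- data.frame(contig = tab$contig, position = as.integer(tab$position),
                     ref = tab$ref, alt = tab$alt, stringsAsFactors = FALSE)
  base$key <- variantKey(base$contig, base$position, base$ref, base$alt)
  gnomad <- base; gnomad$frequency <- parse_freq(tab$gnomad_maf)
  gip <- base; gip$frequency <- parse_freq(tab$gip_aaf)
  cols <- c("contig", "position", "ref", "alt", "frequency", "key")
  list(gnomad = gnomad[!is.na(gnomad$frequency), cols],
       gip = gip[!is.na(gip$frequency), cols])
}

#' @rdname consensusSomaticFixture
#' @param dir directory to copy the fixture TSV into.
#' @return \code{emitFixtureTable}: the destination path, invisibly.
#' @export
emitFixtureTable <- function(dir) {
  src <- system.file("extdata", "consensus_somatic_12.tsv",
                     package = "ConsensusVariants", mustWork = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dir, "consensus_somatic_12.tsv")
  file.copy(src, dest, overwrite = TRUE)
  invisible(dest)
}
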