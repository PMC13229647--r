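#' Simulate a toy reference genome
#'
#' Generates random uniform-base contigs of the requested lengths. Used by
#' the synthetic cohort generator; real references can be supplied as any
#' \code{DNAStringSet} read with \code{\link{readReferenceFasta}}.
#'
#' @param contig_lengths named integer vector of contig lengths.
#' @param seed integer seed; the sequence is fully determined by it.
#' @return A \code{Biostrings::DNAStringSet}.
#' @export
simulateReference <- function(contig_lengths = c(chr1 = 250000L,
                                                 chr2 = 250000L),
                              seed = 1L) {
  set.seed(seed)
  seqs <- vapply(contig_lengths, function(n) {
    paste(.sampleVec(c("A", "C", "G", "T"), n, replace = TRUE),
          collapse = "")
  }, "")
  Biostrings::DNAStringSet(stats::setNames(seqs, names(contig_lengths)))
}

#' Read a reference FASTA
#' @param path FASTA file.
#' @return A \code{DNAStringSet} named by the first word of each header.
#' @export
readReferenceFasta <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Write a reference FASTA
#' @param reference a \code{DNAStringSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReferenceFasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

## named character vector of contig sequences
#' @keywords internal
.referenceAsStrings <- function(reference) {
  if (is.character(reference)) {
    stopifnot(!is.null(names(reference)))
    return(reference)
  }
  stats::setNames(as.character(reference), names(reference))
}
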