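#' Canonical variant key
#'
#' Builds the "contig:position:ref:alt" string used as the exact join key by
#' every matching step (consensus intersection, annotation, frequency and
#' GWAS joins).
#'
#' @param contig,position,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @export
variantKey <- function(contig, position, ref, alt) {
  paste(contig, position, ref, alt, sep = ":")
}

#' @keywords internal
.parseKey <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(contig = vapply(parts, `[`, "", 1L),
             position = as.integer(vapply(parts, `[`, "", 2L)),
             ref = vapply(parts, `[`, "", 3L),
             alt = vapply(parts, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

## sample k elements from x without the scalar-x surprise of sample()
#' @keywords internal
.sampleVec <- function(x, k, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), k, replace = replace, prob = prob)]
}

#' @keywords internal
.stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

## collapse a named count vector to "code=n;code=n"
#' @keywords internal
.encodeReasons <- function(tab) {
  if (!length(tab)) return("")
  paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ";")
}

#' Wilson score confidence-interval upper bound for a proportion
#'
#' Closed-form upper bound of the score-based (Wilson) two-sided confidence
#' interval for a binomial proportion, used by the bona fide CNV filter to
#' bound the population allele frequency from allele counts.
#'
#' @param x successes (allele count), vectorized.
#' @param n trials (allele number), vectorized.
#' @param ci_level two-sided confidence level, default 0.90.
#' @return numeric vector of upper bounds in \[0,1\]; NA where n is 0 or
#'   missing.
#' @examples
#' wilsonUpperBound(10, 10000, 0.90)
#' @export
wilsonUpperBound <- function(x, n, ci_level = 0.90) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  p <- x / n
  ub <- (p + z^2 / (2 * n) +
         z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  ub[!is.finite(n) | n <= 0] <- NA_real_
  pmin(pmax(ub, 0), 1)
}
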