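# Independent brute-force oracles. These deliberately re-derive expected
# results by enumeration / quadratic scans, never by calling the package
# functions they are used to check.

# All VCF-valid representations (p, ref, alt) of applying `alt` at `pos`
# over `ref` to `seqchar`, restricted to candidates that could be minimal:
# position within [pos - window, pos + nchar(ref)] and ref length at most
# nchar(ref). Returns the minimal representation: smallest total allele
# length, then smallest position.
oracleMinimalRep <- function(seqchar, pos, ref, alt, window = 40L) {
  w1 <- max(1L, pos - window)
  w2 <- min(nchar(seqchar), pos + nchar(ref) - 1L + window)
  hap <- paste0(substr(seqchar, w1, pos - 1L), alt,
                substr(seqchar, pos + nchar(ref), w2))
  best <- NULL
  for (p in w1:(pos + nchar(ref))) {
    for (rl in 0:nchar(ref)) {
      if (p + rl - 1L > w2) next
      r <- if (rl == 0L) "" else substr(seqchar, p, p + rl - 1L)
      pre <- substr(seqchar, w1, p - 1L)
      suf <- if (p + rl > w2) "" else substr(seqchar, p + rl, w2)
      if (nchar(hap) < nchar(pre) + nchar(suf)) next
      if (substr(hap, 1L, nchar(pre)) != pre) next
      if (nchar(suf) > 0 &&
          substr(hap, nchar(hap) - nchar(suf) + 1L, nchar(hap)) != suf) next
      a <- substr(hap, nchar(pre) + 1L, nchar(hap) - nchar(suf))
      if (!nzchar(r) || !nzchar(a) || r == a) next
      cand <- list(position = p, ref = r, alt = a,
                   len = nchar(r) + nchar(a))
      if (is.null(best) || cand$len < best$len ||
          (cand$len == best$len && cand$position < best$position))
        best <- cand
    }
  }
  best
}

# Apply a variant to a contig string (sanity checks in round-trip tests).
applyVariant <- function(seqchar, pos, ref, alt) {
  paste0(substr(seqchar, 1L, pos - 1L), alt,
         substr(seqchar, pos + nchar(ref), nchar(seqchar)))
}

# Two-sided exact conditional test on a 2x2 table by full enumeration of all
# tables with the observed margins; p = sum of probabilities of tables no
# more probable than the observed one (with R's 1 + 1e-7 tie tolerance).
oracleExactTest <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0L) return(1)
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- vapply(xs, function(x)
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)), 0)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Wilson upper bound by numerically inverting the score test: the largest p
# with (phat - p)^2 <= z^2 p (1 - p) / n.
oracleWilsonUpper <- function(x, n, ci_level = 0.90) {
  z <- qnorm(1 - (1 - ci_level) / 2)
  phat <- x / n
  if (phat >= 1) return(1)
  f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  eps <- 1e-12
  if (f(1) < 0) return(1)
  uniroot(f, c(phat + eps, 1), tol = 1e-12)$root
}

# Quadratic all-pairs interval overlap scan on 0-based half-open intervals.
oracleOverlapPairs <- function(cohort, population, min_overlap = 1) {
  out <- NULL
  for (i in seq_len(nrow(cohort))) for (j in seq_len(nrow(population))) {
    if (cohort$contig[i] != population$contig[j]) next
    ov <- min(cohort$end[i], population$end[j]) -
      max(cohort$start[i], population$start[j])
    if (ov >= min_overlap)
      out <- rbind(out, data.frame(cohort_idx = i, population_idx = j,
                                   overlap_bp = ov))
  }
  out
}

# Random BED-like interval table.
randomIntervals <- function(n, contigs = c("chr1", "chr2"), span = 100000) {
  start <- floor(runif(n, 0, span))
  data.frame(contig = sample(contigs, n, replace = TRUE),
             start = start, end = start + floor(runif(n, 1, 5000)),
             sv_type = sample(c("DEL", "DUP"), n, replace = TRUE),
             pop_maf = NA_real_, allele_count = NA_real_,
             allele_number = NA_real_,
             sv_id = sprintf("iv_%d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# Small synthetic cohort used across tests.
smallCohort <- function(seed = 11L, n_germ = 40L, n_som = 6L) {
  simulateTruth(cohortConfig(n_samples = 12L, n_malignant = 7L, n_bph = 3L,
                             n_germline_truth = n_germ,
                             n_somatic_truth = n_som,
                             contig_lengths = c(chr1 = 60000L,
                                                chr2 = 60000L),
                             seed = seed))
}
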