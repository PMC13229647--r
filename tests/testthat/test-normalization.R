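ref1 <- list(chr1 = paste0(strrep("T", 1000), "GCAT", strrep("G", 996)))
mkref <- function(seqs) stats::setNames(unlist(seqs), names(seqs))

test_that("shared prefix/suffix trimming reduces an MNP to its core change", {
  calls <- data.frame(contig = "chr1", position = 1001L, ref = "GCAT",
                      alt = "GTAT", stringsAsFactors = FALSE)
  out <- normalizeVariants(calls, mkref(ref1))
  expect_equal(out$position, 1002L)
  expect_equal(out$ref, "C")
  expect_equal(out$alt, "T")
})

test_that("normalization is idempotent on minimal SNVs", {
  calls <- data.frame(contig = "chr1", position = 1002L, ref = "C",
                      alt = "G", stringsAsFactors = FALSE)
  out <- normalizeVariants(calls, mkref(ref1))
  expect_equal(out[, c("position", "ref", "alt")],
               calls[, c("position", "ref", "alt")])
  out2 <- normalizeVariants(out, mkref(ref1))
  expect_equal(out2$key, out$key)
})

test_that("a deletion at the right edge of a dinucleotide tract left-aligns to the oracle's minimal form", {
  seq <- paste0(strrep("A", 50), "G", strrep("CA", 6), "G", strrep("T", 50))
  # delete the final "CA" of the tract: anchor at the last A of (CA)x5
  pos <- 50L + 1L + 10L           # the 5th 'A' of the tract
  refal <- substr(seq, pos, pos + 2L)  # "ACA"
  calls <- data.frame(contig = "c", position = pos, ref = refal,
                      alt = substr(seq, pos, pos), stringsAsFactors = FALSE)
  out <- normalizeVariants(calls, c(c = seq))
  orc <- oracleMinimalRep(seq, pos, refal, calls$alt)
  expect_equal(out$position, orc$position)
  expect_equal(out$ref, orc$ref)
  expect_equal(out$alt, orc$alt)
  expect_lt(out$position, pos)   # it really moved left
})

test_that("all equivalent encodings of random tract indels map to the oracle's minimal key", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (case in 1:120) {
    unit <- paste(sample(bases, sample(1:3, 1), replace = TRUE),
                  collapse = "")
    tract <- strrep(unit, ceiling(30 / nchar(unit)))
    tract <- substr(tract, 1, sample(6:30, 1))
    seq <- paste0(paste(sample(bases, 40, TRUE), collapse = ""), tract,
                  paste(sample(bases, 40, TRUE), collapse = ""))
    # plant an indel somewhere inside the tract
    p <- 40L + sample(nchar(tract) - 4L, 1L)
    l <- sample(1:3, 1)
    if (runif(1) < 0.5) {  # deletion
      refal <- substr(seq, p, p + l); altal <- substr(seq, p, p)
    } else {               # insertion of a rotation of the unit
      refal <- substr(seq, p, p)
      altal <- paste0(refal, strrep(unit, ceiling(l / nchar(unit))))
      altal <- substr(altal, 1, 1 + l)
    }
    if (refal == altal) next
    out <- normalizeVariants(
      data.frame(contig = "c", position = p, ref = refal, alt = altal,
                 stringsAsFactors = FALSE), c(c = seq))
    orc <- oracleMinimalRep(seq, p, refal, altal)
    expect_equal(out$position, orc$position,
                 label = sprintf("case %d position", case))
    expect_equal(out$ref, orc$ref, label = sprintf("case %d ref", case))
    expect_equal(out$alt, orc$alt, label = sprintf("case %d alt", case))
    # and the normalized record reproduces the same haplotype
    expect_equal(applyVariant(seq, out$position, out$ref, out$alt),
                 applyVariant(seq, p, refal, altal))
  }
})

test_that("reference mismatches and underflow are reported as errors", {
  expect_error(normalizeVariants(
    data.frame(contig = "chr1", position = 1001L, ref = "A", alt = "T"),
    mkref(ref1)), "reference mismatch")
  seq <- c(c = "AAAAAAAAAA")
  expect_error(normalizeVariants(
    data.frame(contig = "c", position = 3L, ref = "AA", alt = "A"), seq),
    "underflow")
})

test_that("splitMultiallelic decomposes AD positionally and recodes genotypes", {
  base <- data.frame(contig = "chr1", position = 100L, ref = "A",
                     filter = "PASS", caller = "c1", sample = "S1",
                     dp = 18, gq = 50, stringsAsFactors = FALSE)
  bi <- cbind(base, alt = "C", gt = "0/1", ad = "10,5")
  out <- splitMultiallelic(bi)
  expect_equal(nrow(out), 1L)
  expect_equal(out$ad_ref, 10L)
  expect_equal(out$ad_alt, 5L)
  expect_equal(out$genotype, "het")
  expect_false(out$cross_alt)

  tri <- cbind(base, alt = "C,T", gt = "1/2", ad = "10,5,3")
  out <- splitMultiallelic(tri)
  expect_equal(nrow(out), 2L)
  expect_equal(out$ad_ref, c(10L, 10L))
  expect_equal(out$ad_alt, c(5L, 3L))
  expect_equal(out$genotype, c("het", "het"))
  expect_true(all(out$cross_alt))

  hom2 <- cbind(base, alt = "C,T", gt = "2/2", ad = "10,0,30")
  out <- splitMultiallelic(hom2)
  expect_equal(out$genotype, c("ref", "hom_alt"))

  bad <- cbind(base, alt = "C,T", gt = "1/2", ad = "10,5")
  expect_error(splitMultiallelic(bad), "chr1:100")
})

test_that("allelic balance comes from AD with NA at zero depth", {
  expect_equal(computeAB(16, 4), 0.2)
  expect_equal(computeAB(10, 10), 0.5)
  expect_true(is.na(computeAB(0, 0)))
  expect_true(is.na(computeAB(NA, 5)))
})

test_that("quality filters accumulate all reasons with inclusive boundaries", {
  mk <- function(dp, gq, filter, genotype, ad_ref, ad_alt)
    data.frame(contig = "c", position = 1L, ref = "A", alt = "T",
               dp = dp, gq = gq, filter = filter, genotype = genotype,
               ad_ref = ad_ref, ad_alt = ad_alt, stringsAsFactors = FALSE)
  th <- qualityThresholds()
  # DP=19 fails depth only
  out <- applyQualityFilters(mk(19, 50, "PASS", "hom_alt", 1, 18), th)
  expect_false(out$pass); expect_equal(out$reasons, "low_dp")
  # exact boundaries pass: DP=20, GQ=20, het AB=0.2
  out <- applyQualityFilters(mk(20, 20, "PASS", "het", 16, 4), th)
  expect_true(out$pass); expect_equal(out$reasons, "")
  # non-PASS fails regardless of quality
  out <- applyQualityFilters(mk(100, 90, "LowQual", "hom_alt", 5, 95), th)
  expect_false(out$pass); expect_equal(out$reasons, "not_pass")
  # multiple failures all reported
  out <- applyQualityFilters(mk(10, 10, "LowQual", "het", 19, 1), th)
  expect_setequal(strsplit(out$reasons, ";")[[1]],
                  c("not_pass", "low_dp", "low_gq", "low_ab"))
  # missing DP: strict fails, lenient passes
  out <- applyQualityFilters(mk(NA, 50, "PASS", "hom_alt", 1, 30), th)
  expect_equal(out$reasons, "missing_field")
  out <- applyQualityFilters(mk(NA, 50, "PASS", "hom_alt", 1, 30),
                             qualityThresholds(strict_missing = FALSE))
  expect_true(out$pass)
  # AB applies to hets only
  out <- applyQualityFilters(mk(50, 50, "PASS", "hom_alt", 45, 5), th)
  expect_true(out$pass)
})
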