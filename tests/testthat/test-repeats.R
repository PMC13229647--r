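# Flank-anchored repeat counting, profile building, risk classification and
# the cohort mosaicism summary.

locus <- repeatLocus()
mkRead <- function(n, lf = locus@left_flank, rf = locus@right_flank)
  paste0(lf, strrep("CAG", n), rf)

test_that("constructed reads yield exact counts; failures get reason codes", {
  obs <- countRepeatUnits(c(r1 = mkRead(18)), locus)
  expect_true(obs$spanning)
  expect_equal(obs$repeat_count, 18L)
  # missing right flank
  obs <- countRepeatUnits(substr(mkRead(18), 1, 60), locus)
  expect_false(obs$spanning)
  expect_equal(obs$reason, "no_right_flank")
  # missing left flank
  obs <- countRepeatUnits(paste0(strrep("CAG", 18), locus@right_flank),
                          locus)
  expect_equal(obs$reason, "no_left_flank")
  # interrupted tract
  obs <- countRepeatUnits(paste0(locus@left_flank, "CAGCAACAG",
                                 locus@right_flank), locus)
  expect_false(obs$spanning)
  expect_equal(obs$reason, "interrupted")
  # zero repeats between the flanks is a valid spanning observation
  obs <- countRepeatUnits(mkRead(0), locus)
  expect_true(obs$spanning)
  expect_equal(obs$repeat_count, 0L)
})

test_that("generator round-trip recovers planted counts 5-40 exactly at zero error", {
  set.seed(61)
  for (n in sample(5:40, 15)) {
    reads <- simulateRepeatReads(n, 1, 10, locus, seed = n)
    obs <- countRepeatUnits(reads, locus)
    expect_true(all(obs$spanning))
    expect_true(all(obs$repeat_count == n))
  }
})

test_that("allele support thresholds drive the mosaicism flag", {
  mkObs <- function(hist) {
    counts <- rep(as.integer(names(hist)), hist)
    data.frame(sample = "S", read_id = seq_along(counts), spanning = TRUE,
               repeat_count = counts, reason = "", stringsAsFactors = FALSE)
  }
  p <- buildRepeatProfile(mkObs(c("18" = 10)))
  expect_equal(supportedAlleles(p), 18L)
  expect_false(isMosaic(p))
  # both alleles pass the 3-read and 0.2-fraction thresholds
  p <- buildRepeatProfile(mkObs(c("18" = 10, "24" = 8)))
  expect_equal(supportedAlleles(p), c(18L, 24L))
  expect_true(isMosaic(p))
  # a single stutter read never supports an allele
  p <- buildRepeatProfile(mkObs(c("18" = 10, "19" = 1)))
  expect_equal(supportedAlleles(p), 18L)
  expect_false(isMosaic(p))
  # below the spanning floor the sample is uncallable
  p <- buildRepeatProfile(mkObs(c("18" = 5)),
                          mosaicismParams(min_total_spanning = 10))
  expect_equal(riskClass(p), "uncallable")
})

test_that("raising min_reads_per_allele never adds supported alleles", {
  set.seed(67)
  counts <- sample(10:30, 200, TRUE)
  obs <- data.frame(sample = "S", read_id = seq_along(counts),
                    spanning = TRUE, repeat_count = counts, reason = "",
                    stringsAsFactors = FALSE)
  prev <- NULL
  for (mr in c(1, 3, 5, 10)) {
    p <- buildRepeatProfile(obs, mosaicismParams(
      min_reads_per_allele = mr, min_allele_fraction = 0.01))
    if (!is.null(prev))
      expect_true(all(supportedAlleles(p) %in% prev))
    prev <- supportedAlleles(p)
  }
})

test_that("risk boundary is inclusive at 18 repeats with the any-allele rule", {
  reads18 <- simulateRepeatReads(18, 1, 20, locus, seed = 1)
  p18 <- buildRepeatProfile(countRepeatUnits(reads18, locus, "a"))
  expect_equal(riskClass(p18), "high")
  reads19 <- simulateRepeatReads(19, 1, 20, locus, seed = 1)
  p19 <- buildRepeatProfile(countRepeatUnits(reads19, locus, "b"))
  expect_equal(riskClass(p19), "not-elevated")
  # mosaic {16, 24}: any supported short allele makes the sample high risk
  mix <- simulateRepeatReads(c(16, 24), c(0.5, 0.5), 40, locus, seed = 2)
  pm <- buildRepeatProfile(countRepeatUnits(mix, locus, "c"))
  expect_true(isMosaic(pm))
  expect_equal(riskClass(pm), "high")
})

test_that("profiles are invariant to read order", {
  reads <- simulateRepeatReads(c(15, 22), c(0.5, 0.5), 60, locus, seed = 5)
  p1 <- buildRepeatProfile(countRepeatUnits(reads, locus, "s"))
  p2 <- buildRepeatProfile(countRepeatUnits(rev(reads), locus, "s"))
  expect_identical(repeatHistogram(p1), repeatHistogram(p2))
  expect_identical(supportedAlleles(p1), supportedAlleles(p2))
  expect_identical(riskClass(p1), riskClass(p2))
})

test_that("cohort summary counts mosaic over callable with both denominators", {
  mkP <- function(id, hist, span = sum(hist)) {
    counts <- rep(as.integer(names(hist)), hist)
    obs <- data.frame(sample = id, read_id = seq_along(counts),
                      spanning = TRUE, repeat_count = counts, reason = "",
                      stringsAsFactors = FALSE)
    buildRepeatProfile(obs)
  }
  profiles <- c(lapply(1:4, function(i) mkP(paste0("m", i),
                                            c("16" = 10, "25" = 10))),
                lapply(1:7, function(i) mkP(paste0("s", i), c("20" = 12))),
                list(mkP("u", c("20" = 2))))  # uncallable
  s <- cohortMosaicismSummary(profiles)
  expect_equal(s$n_callable, 11L)
  expect_equal(s$n_mosaic, 4L)
  expect_equal(s$fraction_mosaic_callable, 4 / 11)
  expect_equal(s$fraction_mosaic_all, 4 / 12)
  # all-singleton cohort has zero mosaicism
  s0 <- cohortMosaicismSummary(lapply(1:5, function(i)
    mkP(paste0("x", i), c("21" = 15))))
  expect_equal(s0$fraction_mosaic_callable, 0)
})
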