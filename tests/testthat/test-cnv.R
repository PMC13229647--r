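# Interval intersection, the Wilson-bound bona fide filter, and SNV-in-CNV
# co-localization, all checked against quadratic oracles.

mkSv <- function(contig, start, end, ...) {
  df <- data.frame(contig = contig, start = start, end = end,
                   sv_type = "DEL", pop_maf = NA_real_,
                   allele_count = NA_real_, allele_number = NA_real_,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df$sv_id <- sprintf("sv_%d", seq_len(nrow(df)))
  df
}

test_that("half-open interval semantics: touching intervals do not overlap", {
  cohort <- mkSv("chr1", 100, 200)
  pop <- mkSv("chr1", c(150, 200), c(250, 300))
  pairs <- intersectSvs(cohort, pop)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$population_idx, 1L)
  expect_equal(pairs$overlap_bp, 50)
})

test_that("reciprocal-fraction and sv-type constraints restrict pairs", {
  cohort <- mkSv("chr1", 0, 1000)
  pop <- mkSv("chr1", 900, 10000)  # 100 bp overlap: 10% of cohort, ~1% of pop
  expect_equal(nrow(intersectSvs(cohort, pop)), 1L)
  cfg <- bonaFideConfig(reciprocal_fraction = 0.5)
  expect_equal(nrow(intersectSvs(cohort, pop, cfg)), 0L)
  pop$sv_type <- "DUP"
  expect_equal(nrow(intersectSvs(cohort, pop, match_type = TRUE)), 0L)
})

test_that("random interval sets match the quadratic all-pairs oracle", {
  set.seed(47)
  for (rep in 1:15) {
    cohort <- randomIntervals(sample(20:200, 1))
    pop <- randomIntervals(sample(20:200, 1))
    got <- intersectSvs(cohort, pop)
    want <- oracleOverlapPairs(cohort, pop)
    key <- function(d) if (is.null(d) || !nrow(d)) character() else
      sort(paste(d$cohort_idx, d$population_idx))
    expect_equal(key(got), key(want), label = sprintf("instance %d", rep))
    if (!is.null(want) && nrow(want)) {
      m <- merge(got, want, by = c("cohort_idx", "population_idx"))
      expect_equal(m$overlap_bp.x, m$overlap_bp.y)
    }
  }
})

test_that("the Wilson upper bound matches a numeric score-equation root", {
  for (x in c(0, 1, 5, 10, 25, 50)) for (n in c(50, 1000, 10000)) {
    expect_equal(wilsonUpperBound(x, n, 0.90), oracleWilsonUpper(x, n, 0.90),
                 tolerance = 1e-8, label = sprintf("x=%d n=%d", x, n))
    expect_equal(wilsonUpperBound(x, n, 0.95), oracleWilsonUpper(x, n, 0.95),
                 tolerance = 1e-8)
  }
})

test_that("bona fide calls follow the rarity rule with reason codes", {
  cohort <- mkSv("chr1", c(100, 300, 500, 700), c(200, 400, 600, 800))
  pop <- mkSv("chr1", c(100, 300, 500), c(200, 400, 600),
              pop_maf = c(0.001, 0.10, NA),
              allele_number = c(10000, NA, NA))
  pairs <- intersectSvs(cohort, pop)
  out <- bonaFideFilter(pairs, cohort, pop)
  expect_true(out$bona_fide[1])                 # Wilson bound ~0.0017 < 0.02
  expect_lt(out$ci_upper[1], 0.02)
  expect_false(out$bona_fide[2])                # point estimate too common
  expect_equal(out$reason[2], "not_rare")
  expect_false(out$bona_fide[3])                # no frequency information
  expect_equal(out$reason[3], "no_frequency")
  expect_false(out$bona_fide[4])                # no overlap at all
  expect_equal(out$reason[4], "no_overlap")
  counts <- cnvChromosomeCounts(out)
  expect_equal(counts$n, 1L)
})

test_that("tightening the MAF threshold never grows the bona fide set", {
  set.seed(53)
  cohort <- randomIntervals(100)
  pop <- randomIntervals(150)
  pop$allele_number <- 10000
  pop$allele_count <- rbinom(150, 10000, runif(150, 1e-4, 0.05))
  pop$pop_maf <- pop$allele_count / pop$allele_number
  pairs <- intersectSvs(cohort, pop)
  prev <- NULL
  for (thr in c(0.05, 0.02, 0.01, 0.005)) {
    bf <- bonaFideFilter(pairs, cohort, pop, bonaFideConfig(thr))
    ids <- bf$cohort_id[bf$bona_fide]
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("SNV-in-CNV respects the half-open boundary convention", {
  cnvs <- mkSv("chr1", 100, 200)
  inside <- snvInCnv(data.frame(contig = "chr1", position = 150L), cnvs)
  expect_equal(nrow(inside), 1L)
  # the exclusive end is outside; the inclusive start and end-1 are inside
  expect_equal(nrow(snvInCnv(data.frame(contig = "chr1", position = 200L),
                             cnvs)), 0L)
  expect_equal(nrow(snvInCnv(data.frame(contig = "chr1", position = 199L),
                             cnvs)), 1L)
  expect_equal(nrow(snvInCnv(data.frame(contig = "chr1", position = 100L),
                             cnvs)), 1L)
})

test_that("random SNV placements match the brute-force scan", {
  set.seed(59)
  for (rep in 1:15) {
    cnvs <- randomIntervals(sample(20:100, 1))
    snvs <- data.frame(contig = sample(c("chr1", "chr2"), 100, TRUE),
                       position = sample(1:105000, 100),
                       stringsAsFactors = FALSE)
    got <- snvInCnv(snvs, cnvs)
    want <- 0L
    for (i in seq_len(nrow(snvs))) for (j in seq_len(nrow(cnvs)))
      if (snvs$contig[i] == cnvs$contig[j] &&
          snvs$position[i] >= cnvs$start[j] &&
          snvs$position[i] < cnvs$end[j]) want <- want + 1L
    expect_equal(nrow(got), want)
  }
})

test_that("malformed intervals are rejected when reading SV tables", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("contig\tstart\tend\tsv_type", "chr1\t200\t100\tDEL"), p)
  expect_error(readSvTable(p, "cohort"), "malformed interval")
})
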