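# Generator contracts: determinism, structural invariants of the planted
# truth, noise calibration, and representation styles that normalize back to
# their truth keys.

test_that("identical config and seed give byte-identical outputs", {
  ch1 <- smallCohort(seed = 5L)
  ch2 <- smallCohort(seed = 5L)
  expect_identical(truthVariants(ch1), truthVariants(ch2))
  expect_identical(truthGenotypes(ch1), truthGenotypes(ch2))
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- emitCallerVcfs(ch1, noiseFreeProfiles(), d1)
  m2 <- emitCallerVcfs(ch2, noiseFreeProfiles(), d2)
  for (i in seq_len(nrow(m1)))
    expect_identical(readLines(m1$path[i]), readLines(m2$path[i]))
  p1 <- emitAnnotationTables(ch1, d1)
  p2 <- emitAnnotationTables(ch2, d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
})

test_that("zero somatic truth variants is a valid empty case", {
  ch <- simulateTruth(cohortConfig(n_samples = 8L, n_malignant = 5L,
                                   n_bph = 2L, n_germline_truth = 10L,
                                   n_somatic_truth = 0L,
                                   contig_lengths = c(chr1 = 30000L),
                                   seed = 3L))
  expect_equal(sum(truthVariants(ch)$origin == "somatic"), 0L)
})

test_that("somatic carriers are malignant-only with the grade-linked zygosity rule", {
  ch <- smallCohort(seed = 9L, n_som = 12L)
  truth <- truthVariants(ch); gt <- truthGenotypes(ch)
  smp <- cohortSamples(ch)
  som_keys <- truth$key[truth$origin == "somatic"]
  sg <- gt[gt$key %in% som_keys, ]
  tissue <- smp$tissue[match(sg$sample_id, smp$sample_id)]
  expect_true(all(tissue == "malignant"))
  grade <- smp$grade_group[match(sg$sample_id, smp$sample_id)]
  expect_true(all(sg$genotype[grade == "high"] == "hom_alt"))
  expect_true(all(sg$genotype[grade != "high"] == "het"))
})

test_that("non-normalized distributions are rejected at construction", {
  expect_error(cohortConfig(gleason_distribution = c("4+4" = 0.5,
                                                     "3+3" = 0.4)),
               "sum to 1")
  expect_error(cohortConfig(sharing_distribution = c("1" = 1)),
               "2..n_samples")
})

test_that("uniform sharing counts recover the closed-form mean", {
  n <- 49L
  cfg <- cohortConfig(n_samples = n, n_malignant = 30L, n_bph = 5L,
                      n_germline_truth = 10000L, n_somatic_truth = 0L,
                      contig_lengths = c(chr1 = 300000L, chr2 = 300000L),
                      seed = 21L)
  ch <- simulateTruth(cfg)
  counts <- truthVariants(ch)$n_carriers
  # uniform on {2..49}: mean 25.5, var ((48^2 - 1)/12)
  se <- sqrt((48^2 - 1) / 12 / length(counts))
  expect_lt(abs(mean(counts) - (2 + 49) / 2), 3 * se)
})

test_that("noise-free caller VCFs contain exactly each sample's truth set", {
  ch <- smallCohort(seed = 13L)
  d <- file.path(tempdir(), "nf"); unlink(d, recursive = TRUE)
  man <- emitCallerVcfs(ch, noiseFreeProfiles(), d)
  gt <- truthGenotypes(ch)
  for (i in sample(nrow(man), 4)) {
    calls <- readCallerVcf(man$path[i])
    norm <- normalizeVariants(splitMultiallelic(calls), cohortReference(ch))
    want <- sort(gt$key[gt$sample_id == man$sample[i]])
    expect_equal(sort(norm$key), want)
  }
})

test_that("right-shifted indel records differ in position but normalize back to the truth key", {
  seqs <- c(c = paste0(strrep("G", 30), "A", strrep("CT", 8), "A",
                       strrep("G", 30)))
  # truth: left-aligned deletion of one CT unit (anchor the A before tract)
  pos <- 31L
  truth <- data.frame(contig = "c", position = pos,
                      ref = substr(seqs[["c"]], pos, pos + 2L),
                      alt = "A", stringsAsFactors = FALSE)
  shifted <- ConsensusVariants:::.rightShift(seqs[["c"]], truth$position,
                                             truth$ref, truth$alt)
  expect_gt(shifted$position, truth$position)
  back <- normalizeVariants(
    data.frame(contig = "c", position = shifted$position, ref = shifted$ref,
               alt = shifted$alt, stringsAsFactors = FALSE), seqs)
  expect_equal(back$position, truth$position)
  expect_equal(back$ref, truth$ref)
  expect_equal(back$alt, truth$alt)
  # and both encodings are equivalent on the haplotype
  expect_equal(applyVariant(seqs[["c"]], shifted$position, shifted$ref,
                            shifted$alt),
               applyVariant(seqs[["c"]], truth$position, truth$ref,
                            truth$alt))
})

test_that("a non-PASS fraction of 0.1 lands within binomial 99% bounds", {
  ch <- smallCohort(seed = 17L, n_germ = 300L)
  prof <- list(callerProfile("cx", nonpass_fraction = 0.1, depth_min = 30))
  d <- file.path(tempdir(), "np"); unlink(d, recursive = TRUE)
  man <- emitCallerVcfs(ch, prof, d)
  raw <- do.call(rbind, lapply(man$path, readCallerVcf))
  n <- nrow(raw)
  k <- sum(raw$filter != "PASS")
  bounds <- qbinom(c(0.005, 0.995), n, 0.1)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("decoy fraction zero means every annotation row matches a truth key", {
  ch <- smallCohort(seed = 23L)
  d <- file.path(tempdir(), "dec0"); unlink(d, recursive = TRUE)
  paths <- emitAnnotationTables(ch, d, decoy_fraction = 0)
  ann <- loadAnnotationTable(paths$clinvar, "clinvar")
  expect_true(all(ann$key %in% truthVariants(ch)$key))
  gn <- loadFrequencyTable(paths$gnomad)
  expect_true(all(gn$key %in% truthVariants(ch)$key))
  # planted not-reported MAFs have no row in the gnomAD-like table
  nr_keys <- truthVariants(ch)$key[is.na(truthVariants(ch)$gnomad_maf)]
  expect_false(any(nr_keys %in% gn$key))
})

test_that("repeat reads are exact at zero error and empty at zero reads", {
  locus <- repeatLocus()
  reads <- simulateRepeatReads(18, 1, 50, locus, seed = 2)
  expect_length(reads, 50)
  expect_true(all(reads == paste0(locus@left_flank, strrep("CAG", 18),
                                  locus@right_flank)))
  expect_length(simulateRepeatReads(18, 1, 0, locus, seed = 2), 0)
})

test_that("mixture fractions are recovered within binomial 99% bounds", {
  reads <- simulateRepeatReads(c(18, 24), c(0.6, 0.4), 1000, seed = 31)
  obs <- countRepeatUnits(reads)
  k18 <- sum(obs$repeat_count == 18, na.rm = TRUE)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.6)
  expect_gte(k18, bounds[1])
  expect_lte(k18, bounds[2])
})
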