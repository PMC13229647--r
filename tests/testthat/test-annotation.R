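# Annotation matching, classification filtering and the somatic/germline
# partition, anchored on the packaged 12-variant fixture.

test_that("the packaged fixture parses to 12 records with the printed class counts", {
  fx <- fixtureAnnotationRecords()
  expect_equal(nrow(fx), 12L)
  counts <- table(fx$classification)
  expect_equal(counts[["Pathogenic"]], 4L)
  expect_equal(counts[["Likely-pathogenic"]], 1L)
  expect_equal(counts[["Likely-benign"]], 1L)
  expect_equal(counts[["Benign"]], 1L)
  expect_equal(counts[["VUS"]], 4L)
  expect_equal(counts[["Conflicting"]], 1L)
  # raw synonym strings map onto the closed vocabulary
  raw <- consensusSomaticFixture()
  expect_equal(fx$classification[raw$rsid == "rs202160435"], "Conflicting")
  expect_equal(fx$classification[raw$rsid == "rs121913364"],
               "Likely-pathogenic")
})

test_that("loadAnnotationTable validates, maps synonyms and collapses conflicts", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("contig\tposition\tref\talt\trsid\tgene\tclassification\torigin",
               "chr1\t100\tA\tT\trs1\tG1\tConflicting pathogenicity\tsomatic",
               "chr1\t200\tC\tG\trs2\tG2\tPathogenic\tgermline",
               "chr1\t200\tC\tG\trs2\tG2\tBenign\tgermline"), p)
  ann <- loadAnnotationTable(p, "clinvar")
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$classification[ann$position == 100], "Conflicting")
  # duplicate key with conflicting classes collapses to Conflicting
  expect_equal(ann$classification[ann$position == 200], "Conflicting")
  # empty file with a valid header gives an empty list
  writeLines("contig\tposition\tref\talt\trsid\tgene\tclassification\torigin",
             p)
  expect_equal(nrow(loadAnnotationTable(p, "clinvar")), 0L)
  # missing required column is a schema error
  writeLines(c("contig\tposition\tref", "chr1\t1\tA"), p)
  expect_error(loadAnnotationTable(p, "clinvar"), "required column")
})

test_that("matching is by position + alt with a ref consistency check", {
  fx <- fixtureAnnotationRecords()
  cons <- data.frame(contig = "17", position = 7676154L, ref = "G",
                     alt = "C", stringsAsFactors = FALSE)
  out <- matchVariants(cons, fx)
  expect_true(out$matched)
  expect_equal(out$rsid, "rs1042522")
  expect_equal(out$classification, "Benign")
  # allele mismatch: same position, different alt
  cons$alt <- "T"
  expect_false(matchVariants(cons, fx)$matched)
  # ref disagreement at a matched position+alt warns and does not match
  cons <- data.frame(contig = "17", position = 7676154L, ref = "A",
                     alt = "C", stringsAsFactors = FALSE)
  expect_warning(out <- matchVariants(cons, fx), "disagreement")
  expect_false(out$matched)
})

test_that("random key sets match exactly the all-pairs oracle", {
  set.seed(19)
  for (rep in 1:20) {
    vpos <- sample(1:60, sample(5:50, 1))
    apos <- sample(1:60, sample(5:50, 1))
    valt <- sample(c("T", "G"), length(vpos), TRUE)
    aalt <- sample(c("T", "G"), length(apos), TRUE)
    vars <- data.frame(contig = "chr1", position = vpos, ref = "A",
                       alt = valt, stringsAsFactors = FALSE)
    ann <- data.frame(contig = "chr1", position = apos, ref = "A",
                      alt = aalt, rsid = NA, gene = NA,
                      classification = "VUS", origin = "unknown",
                      source = "clinvar",
                      key = variantKey("chr1", apos, "A", aalt),
                      stringsAsFactors = FALSE)
    ann <- ann[!duplicated(ann$key), ]
    got <- matchVariants(vars, ann)$matched
    want <- vapply(seq_len(nrow(vars)), function(i)
      any(ann$position == vars$position[i] & ann$alt == vars$alt[i]), TRUE)
    expect_equal(got, want)
  }
})

test_that("classification filtering reproduces the fixture's headline counts", {
  fx <- fixtureAnnotationRecords()
  non_benign <- filterByClassification(
    fx, setdiff(unique(classificationVocabulary()), "Benign"))
  expect_equal(nrow(non_benign), 11L)
  expect_equal(nrow(filterByClassification(fx, "VUS")), 4L)
  expect_equal(nrow(filterByClassification(
    fx, unique(classificationVocabulary()))), nrow(fx))
  expect_error(filterByClassification(fx, character()), "at least one")
})

test_that("the somatic/germline partition follows origin + BPH-carrier rules", {
  samples <- sampleMetadata(data.frame(
    sample_id = c("M1", "M2", "B1"), tissue = c("malignant", "malignant",
                                                "BPH"),
    gleason_primary = c(4L, 4L, 2L), gleason_secondary = c(4L, 3L, 3L)))
  classified <- data.frame(
    key = c("k1", "k2", "k3", "k4"),
    origin = c("somatic", "somatic", "germline", "unknown"),
    stringsAsFactors = FALSE)
  carriers <- data.frame(
    key = c("k1", "k1", "k2", "k2", "k3", "k4"),
    sample = c("M1", "M2", "M1", "B1", "M1", "B1"),
    stringsAsFactors = FALSE)
  part <- partitionSomaticGermline(classified, carriers, samples)
  expect_equal(part$somatic$key, "k1")          # somatic origin, no BPH
  expect_true("k3" %in% part$germline$key)      # germline origin
  expect_true("k4" %in% part$germline$key)      # unknown origin + BPH carrier
  expect_equal(part$unresolved$key, "k2")       # somatic origin demoted
  # exhaustive and disjoint
  expect_equal(nrow(part$somatic) + nrow(part$germline) +
                 nrow(part$unresolved), nrow(classified))
  expect_equal(sort(c(part$somatic$key, part$germline$key,
                      part$unresolved$key)), sort(classified$key))
})

test_that("partition is exhaustive and disjoint on random cohorts", {
  set.seed(29)
  samples <- sampleMetadata(data.frame(
    sample_id = sprintf("S%d", 1:10),
    tissue = c(rep("malignant", 7), rep("BPH", 3)),
    gleason_primary = c(rep(4L, 7), rep(2L, 3)),
    gleason_secondary = c(rep(3L, 7), rep(3L, 3))))
  for (rep in 1:10) {
    keys <- sprintf("k%d", 1:30)
    classified <- data.frame(
      key = keys, origin = sample(c("somatic", "germline", "both",
                                    "unknown"), 30, TRUE),
      stringsAsFactors = FALSE)
    carriers <- data.frame(
      key = sample(keys, 80, TRUE),
      sample = sample(samples$sample_id, 80, TRUE),
      stringsAsFactors = FALSE)
    part <- partitionSomaticGermline(classified, carriers, samples)
    expect_equal(nrow(part$somatic) + nrow(part$germline) +
                   nrow(part$unresolved), 30L)
    expect_false(any(duplicated(c(part$somatic$key, part$germline$key,
                                  part$unresolved$key))))
    # no somatic call carries a BPH sample
    bph <- samples$sample_id[samples$tissue == "BPH"]
    for (k in part$somatic$key)
      expect_false(any(carriers$sample[carriers$key == k] %in% bph))
  }
})
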