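test_that("classify_variant agrees with the hand-labelled fixture rows", {
  raw <- read.delim(mrdpos_fixture_path(), colClasses = "character")
  raw$pdot[is.na(raw$pdot)] <- ""
  expect_equal(classify_variant(raw$cdot, raw$pdot), fixture_hand_classes)
})

test_that("classify_variant covers each rule and never throws", {
  expect_equal(classify_variant("c.6596A>T", "p.Q2199L"), "missense")
  expect_equal(classify_variant("c.6995C>G", "p.S2332*"), "stopgain")
  expect_equal(classify_variant("c.4427del", "p.N1476Tfs*12"),
               "frameshift_indel")
  expect_equal(classify_variant("c.1209_1211del", "p.E404del"),
               "nonframeshift_indel")
  expect_equal(classify_variant("c.100_101insAAA", "p.K34_G35insQ"),
               "nonframeshift_indel")
  expect_equal(classify_variant("c.-124C>T", ""), "promoter")
  expect_equal(classify_variant("c.97-2A>T", ""), "splice_site")
  expect_equal(classify_variant("c.97+1G>T", ""), "splice_site")
  expect_equal(classify_variant("c.300C>T", "p.F100F"), "synonymous")
  expect_equal(classify_variant("gibberish", "alsogibberish"), "other")
  expect_equal(classify_variant("c.97-8A>T", ""), "other")
})

test_that("fixture table loads with 13 variants over 6 samples", {
  tab <- mrdpos_fixture_cohort()
  expect_s3_class(tab, "ctdna_cohort")
  expect_equal(nrow(tab$variants), 13)
  expect_equal(nrow(tab$samples), 6)
  expect_equal(nrow(attr(tab, "row_errors")), 0)
})

test_that("rows with invalid VAF are rejected with row-indexed diagnostics", {
  raw <- readLines(mrdpos_fixture_path())
  bad <- sub("0.002152", "1.5", raw[5], fixed = TRUE)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(raw[1:4], bad, raw[6:14]), tmp)
  expect_warning(tab <- read_variant_table(tmp), "1 of 13 rows rejected")
  expect_equal(nrow(tab$variants), 12)
  errs <- attr(tab, "row_errors")
  expect_equal(errs$row, 4L)
  expect_match(errs$message, "vaf")
})

test_that("a header-only file yields an empty table and a missing column errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(readLines(mrdpos_fixture_path())[1], tmp)
  tab <- read_variant_table(tmp)
  expect_equal(nrow(tab$variants), 0)
  writeLines("sample_id\tgene\tcdot\tvaf", tmp) # no variant_type
  expect_error(read_variant_table(tmp), "missing column")
})

test_that("write/read round trip reproduces every variant field", {
  tab <- mrdpos_fixture_cohort()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(tab, tmp)
  back <- read_variant_table(tmp)
  expect_identical(back$variants, tab$variants)
})

test_that("minimal VCF reading infers types and expands multi-ALT records", {
  v <- read_minimal_vcf(system.file("extdata", "example_single_sample.vcf",
                                    package = "hccMRD"))
  expect_equal(nrow(v$variants), 4)
  expect_equal(v$variants$variant_type,
               c("Substitution", "Deletion", "Substitution",
                 "Substitution"))
  expect_equal(v$variants$vaf, c(0.0103, 0.0042, 0.0031, 0.0012))
  # hand-expanded multi-ALT record: two calls at the same position
  expect_equal(sum(grepl("151945072", v$variants$cdot)), 2)
  expect_equal(v$variants$gene[1], "TP53")
  expect_error(
    read_minimal_vcf(system.file("extdata", "example_single_sample.vcf",
                                 package = "hccMRD"), vaf_field = "ZZ"),
    "ZZ")
})

test_that("retention filter keeps hotspots only when asked and is idempotent", {
  tab <- mrdpos_fixture_cohort()
  on <- retention_filter(tab, keep_noncoding_hotspots = TRUE)
  off <- retention_filter(tab, keep_noncoding_hotspots = FALSE)
  expect_equal(nrow(on$variants), 13)
  expect_equal(nrow(off$variants), 11)
  expect_false(any(off$variants$variant_class %in%
                     NONCODING_HOTSPOT_CLASSES))
  expect_identical(retention_filter(on)$variants, on$variants)
  syn <- cohort_variant_table(data.frame(
    sample_id = "s", gene = "TP53", cdot = "c.300C>T", pdot = "p.F100F",
    vaf = 0.1, variant_type = "Substitution"))
  expect_equal(nrow(retention_filter(syn)$variants), 0)
})

test_that("protein changes parse to position and kind without crashing", {
  res <- parse_protein_change(c("p.Q2199L", "p.N1476Tfs*12",
                                "p.M2364Cfs*10", "p.S2332*", "p.E404del",
                                "p.K34_G35insQ", "nonsense"))
  expect_equal(res$position[1:6], c(2199L, 1476L, 2364L, 2332L, 404L, 34L))
  expect_equal(res$kind[1:6],
               c("substitution", "frameshift", "frameshift", "nonsense",
                 "inframe_del", "inframe_ins"))
  expect_false(res$ok[7])
  expect_true(all(res$ok[1:6]))
})

test_that("gene symbol aliases are normalized and invariants enforced", {
  expect_equal(normalize_gene(c(" RMB10 ", "TP53")), c("RBM10", "TP53"))
  expect_error(cohort_variant_table(
    data.frame(sample_id = "s", gene = "TP53", cdot = "c.1A>T",
               vaf = 0.5, variant_type = "Substitution"),
    samples = data.frame(sample_id = "other")),
    "unknown sample")
  expect_error(cohort_variant_table(
    data.frame(sample_id = "s", gene = "TP53", cdot = "c.1A>T",
               vaf = 0.5, variant_type = "Substitution"),
    covered_genes = list(custom = c("APC"))),
    "not covered")
})
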