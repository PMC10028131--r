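test_that("gene frequencies collapse within-sample multiplicity", {
  v <- data.frame(
    sample_id = c("s1", "s1"), gene = "TP53",
    cdot = c("c.747G>T", "c.607G>A"), pdot = c("p.R249S", "p.V203M"),
    vaf = 0.01, variant_type = "Substitution")
  co <- cohort_variant_table(v, samples = data.frame(sample_id = c("s1", "s2")))
  f <- gene_mutation_frequency(co)
  expect_equal(f$n_mutated, 1L)
  expect_equal(f$frequency, 0.5)
})

test_that("fixture cohort frequencies match hand counts", {
  f <- gene_mutation_frequency(mrdpos_fixture_cohort())
  expect_equal(f$frequency[f$gene == "TP53"], 3 / 6)
  expect_equal(f$n_mutated[f$gene == "EZH2"], 2L)
  expect_equal(f$n_eligible, rep(6L, nrow(f)))
})

test_that("panel-aware denominators count only covered samples", {
  v <- data.frame(sample_id = c("a", "b"), gene = c("TP53", "KEAP1"),
                  cdot = "c.3G>T", pdot = c("p.M1I", "p.M1I"),
                  vaf = 0.1, variant_type = "Substitution")
  samples <- data.frame(sample_id = c("a", "b", "c"),
                        panel_id = c("panel381", "panel733", "panel381"))
  cov <- list(panel381 = c("TP53"), panel733 = c("TP53", "KEAP1"))
  co <- cohort_variant_table(v, samples, covered_genes = cov)
  f <- gene_mutation_frequency(co)
  expect_equal(f$n_eligible[f$gene == "TP53"], 3L)
  expect_equal(f$n_eligible[f$gene == "KEAP1"], 1L)
  expect_equal(f$frequency[f$gene == "KEAP1"], 1)
  fc <- gene_mutation_frequency(co, denominator = "cohort")
  expect_equal(fc$n_eligible, rep(3L, 2))
})

test_that("detection rate counts samples with at least one retained variant", {
  expect_equal(detection_rate(mrdpos_fixture_cohort()), 1)
  co <- cohort_variant_table(NULL,
                             samples = data.frame(sample_id = c("a", "b")))
  expect_equal(detection_rate(co), 0)
  expect_error(detection_rate(cohort_variant_table(NULL)), "empty cohort")
  # 464 of 493: printed cohort-scale check of the arithmetic
  samp <- data.frame(sample_id = sprintf("s%03d", 1:493))
  v <- data.frame(sample_id = samp$sample_id[1:464], gene = "TP53",
                  cdot = "c.747G>T", pdot = "p.R249S", vaf = 0.01,
                  variant_type = "Substitution")
  expect_equal(round(detection_rate(cohort_variant_table(v, samp)), 3),
               0.941)
})

test_that("variant class summary matches the hand classification", {
  cls <- variant_class_summary(mrdpos_fixture_cohort())
  expect_equal(cls[["missense"]], 4L)
  expect_equal(cls[["stopgain"]], 2L)
  expect_equal(cls[["frameshift_indel"]], 4L)
  expect_equal(cls[["nonframeshift_indel"]], 1L)
  expect_equal(cls[["promoter"]], 1L)
  expect_equal(cls[["splice_site"]], 1L)
  expect_equal(sum(cls), 13L)
})

test_that("SNV classes collapse purine references onto pyrimidines", {
  snv <- snv_class_summary(mrdpos_fixture_cohort())
  # hand-collapsed fixture spectrum: A>T,T>G,G>A,C>G,C>G,C>T,G>T,A>T
  expect_equal(snv[["C>T"]], 2L)  # c.-124C>T and c.607G>A collapsed
  expect_equal(snv[["C>A"]], 1L)  # c.747G>T collapsed
  expect_equal(snv[["T>A"]], 2L)
  expect_equal(snv[["C>G"]], 2L)
  expect_equal(snv[["T>G"]], 1L)
  expect_equal(sum(snv), 8L)     # 5 deletions carry no ref>alt
})

test_that("SNV collapsing respects reverse complementation", {
  for (cls in c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")) {
    ref <- substr(cls, 1, 1); alt <- substr(cls, 3, 3)
    rc <- paste0(COMPLEMENT[[ref]], ">", COMPLEMENT[[alt]])
    fw <- hccMRD:::snv_class_of(paste0("c.100", cls))
    bw <- hccMRD:::snv_class_of(paste0("c.100", rc))
    expect_equal(fw, cls)
    expect_equal(bw, cls)
  }
})

test_that("variants per sample reproduces the hand count", {
  v <- variants_per_sample(mrdpos_fixture_cohort())
  expect_equal(sort(unname(v$counts)), c(1L, 1L, 2L, 3L, 3L, 3L))
  expect_equal(v$median, 2.5)
  expect_equal(c(v$min, v$max), c(1L, 3L))
})

test_that("pathway summary counts affected samples by membership union", {
  co <- mrdpos_fixture_cohort()
  ps <- pathway_summary(co, list(TP53_pw = c("TP53")))
  expect_equal(ps$n_affected_samples, 3L)
  expect_warning(
    ps2 <- pathway_summary(co, list(x = c("TP53", "NOSUCHGENE"))),
    "never observed")
  expect_equal(ps2$n_unknown_genes, 1L)
  expect_equal(nrow(pathway_summary(co, list())), 0L)
  # hand counts over two disjoint pathways covering every mutated gene;
  # together they reach all 6 samples
  ps3 <- pathway_summary(co, list(
    a = c("TP53", "TERT", "NF1"), b = c("CREBBP", "EZH2", "GLI3", "APC")))
  expect_equal(ps3$n_affected_samples, c(5L, 3L))
  expect_equal(ps3$n_mutated_genes, c(3L, 4L))
})

test_that("gene sets load from GMT files", {
  gs <- read_gene_sets(system.file("extdata", "hcc_pathways.gmt",
                                   package = "hccMRD"))
  expect_true("TP53" %in% gs$TP53)
  expect_equal(length(gs), 6)
})

test_that("perfect co-occurrence and exclusivity are labelled with oracle p", {
  mk <- function(genes_by_sample) {
    rows <- do.call(rbind, lapply(names(genes_by_sample), function(s) {
      gs <- genes_by_sample[[s]]
      if (!length(gs)) return(NULL)
      data.frame(sample_id = s, gene = gs, cdot = "c.3G>T", pdot = "p.M1I",
                 vaf = 0.1, variant_type = "Substitution")
    }))
    cohort_variant_table(rows, samples = data.frame(
      sample_id = names(genes_by_sample)))
  }
  ids <- sprintf("s%02d", 1:10)
  both <- stats::setNames(c(rep(list(c("A", "B")), 5),
                            rep(list(character()), 5)), ids)
  co <- mk(both)
  si <- somatic_interactions(co, top_n = 2)
  expect_equal(si$odds_ratio, Inf)
  expect_equal(si$label, "co_occurring")
  expect_equal(si$p_value, oracle_fisher_p(5, 0, 0, 5), tolerance = 1e-12)

  excl <- stats::setNames(c(rep(list("A"), 5), rep(list("B"), 5)), ids)
  si2 <- somatic_interactions(mk(excl), top_n = 2)
  expect_equal(si2$odds_ratio, 0)
  expect_equal(si2$label, "mutually_exclusive")
})

test_that("interaction p-values and BH adjustment match enumeration oracles", {
  set.seed(77)
  for (r in 1:25) {
    n <- sample(8:30, 1)
    g <- matrix(runif(n * 3) < runif(1, 0.2, 0.7), n, 3)
    v <- do.call(rbind, lapply(1:3, function(j) {
      s <- which(g[, j])
      if (!length(s)) return(NULL)
      data.frame(sample_id = sprintf("s%02d", s), gene = LETTERS[j],
                 cdot = "c.3G>T", pdot = "p.M1I", vaf = 0.1,
                 variant_type = "Substitution")
    }))
    if (is.null(v) || length(unique(v$gene)) < 2) next
    co <- cohort_variant_table(
      v, samples = data.frame(sample_id = sprintf("s%02d", 1:n)))
    si <- somatic_interactions(co, top_n = 3)
    for (i in seq_len(nrow(si))) {
      expect_equal(si$p_value[i],
                   oracle_fisher_p(si$n_both[i], si$n_a_only[i],
                                   si$n_b_only[i], si$n_neither[i]),
                   tolerance = 1e-10)
    }
    expect_equal(si$adjusted_p, oracle_bh(si$p_value), tolerance = 1e-12)
  }
})

test_that("driver clustering scores hotspot, dispersed and mixed genes", {
  mk_gene <- function(gene, residues) data.frame(
    sample_id = sprintf("%s_%d", gene, seq_along(residues)), gene = gene,
    cdot = "c.3G>T", pdot = sprintf("p.A%dV", residues), vaf = 0.1,
    variant_type = "Substitution")
  co <- cohort_variant_table(rbind(
    mk_gene("HOT", rep(249, 6)),
    mk_gene("FLAT", c(10, 25, 40, 55, 70, 90)),
    mk_gene("MIX", c(10, 10, 12, 40, 41, 90))))
  dc <- driver_clustering(co, min_mutations = 5, gap = 5)
  expect_equal(dc$clustering_score[dc$gene == "HOT"], 1)
  expect_equal(dc$n_clusters[dc$gene == "HOT"], 1L)
  expect_equal(dc$clustering_score[dc$gene == "FLAT"], 0)
  # hand trace: seed at 10 extends to 12; the {40,41} pair has no seed
  expect_equal(dc$clustering_score[dc$gene == "MIX"], 0.5)
  cl <- attr(dc, "clusters")$MIX
  expect_equal(cl$start_residue, 10)
  expect_equal(cl$end_residue, 12)
  expect_equal(cl$n, 3)
  expect_equal(dc$gene[which.max(dc$z_score)], "HOT")
  # no qualifying genes -> empty result, not an error
  co2 <- cohort_variant_table(mk_gene("X", c(1, 2)))
  expect_equal(nrow(driver_clustering(co2)), 0)
})

test_that("frequencies are invariant to duplicating a sample's variants", {
  co <- mrdpos_fixture_cohort()
  dup <- co$variants
  co2 <- cohort_variant_table(rbind(dup, dup), samples = co$samples)
  expect_equal(gene_mutation_frequency(co2)$frequency,
               gene_mutation_frequency(co)$frequency)
  expect_equal(detection_rate(co2), detection_rate(co))
})
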