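AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
         "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default per-gene marginal mutation frequencies for the synthetic
#' Chinese-HCC ctDNA cohort
#'
#' The five most frequent genes carry their published cohort
#' frequencies (TP53 0.451, LRP1B 0.202, TERT 0.202, FAT1 0.162,
#' CTNNB1 0.134); the remaining monitoring-panel and control-screen
#' genes are placed in the 5-12% band so the default frequency screen
#' reproduces the shipped 13-gene panel, and a 268-gene placeholder
#' tail (`GENE001`...) with geometrically decaying low frequencies
#' fills the panel to 294 genes. The tail is scaled so that the summed
#' marginals put the median variant burden of mutation-bearing samples
#' at 4.
#'
#' @return named numeric vector of marginal mutation probabilities.
#' @export
default_gene_freqs <- function() {
  top5 <- c(TP53 = 0.451, LRP1B = 0.202, TERT = 0.202, FAT1 = 0.162,
            CTNNB1 = 0.134)
  panel_rest <- c(APC = 0.095, CDKN2A = 0.085, CREBBP = 0.060,
                  EZH2 = 0.055, GLI3 = 0.060, NF1 = 0.090,
                  NOTCH1 = 0.070, NOTCH2 = 0.065, NTRK3 = 0.075,
                  RBM10 = 0.080)
  screen_rest <- c(AR = 0.075, ARID1A = 0.110, ATM = 0.090,
                   BRCA2 = 0.080, ERBB2 = 0.065, FAM135B = 0.070,
                   MSH6 = 0.055, NOTCH3 = 0.060, RB1 = 0.100,
                   SPEN = 0.065, TSC2 = 0.060)
  tail_n <- 294 - length(top5) - length(panel_rest) - length(screen_rest)
  tail <- 0.03 * 0.97^seq_len(tail_n)
  names(tail) <- sprintf("GENE%03d", seq_len(tail_n))
  c(top5, panel_rest, screen_rest, tail)
}

#' Configuration for the synthetic ctDNA cohort generator
#'
#' The generator is a zero-inflated per-gene occurrence model: a sample
#' sheds detectable ctDNA with probability `detection_rate`; a shedding
#' sample mutates each gene independently with a calibrated conditional
#' probability such that the marginal per-gene mutation frequency
#' equals `gene_freqs` exactly (the calibration solves the fixed point
#' induced by conditioning shedding samples on carrying at least one
#' mutation); each mutated gene carries `1 + Geometric(extra_rate)`
#' variants, capped so no sample exceeds `max_variants`. VAFs are drawn
#' from a truncated log-normal; variant classes and base-substitution
#' classes from the given probability vectors, with internally
#' consistent HGVS strings synthesized per variant.
#'
#' @param n_samples cohort size; default 493.
#' @param gene_freqs named marginal mutation probabilities; default
#'   [default_gene_freqs()].
#' @param detection_rate fraction of samples with >= 1 mutation;
#'   default 464/493.
#' @param extra_rate geometric probability of extra variants per
#'   mutated gene; default 0.08.
#' @param max_variants per-sample variant cap; default 33.
#' @param vaf_meanlog,vaf_sdlog,vaf_min,vaf_max truncated log-normal
#'   VAF parameters; defaults median 0.004 on \[5e-4, 0.3\].
#' @param class_probs named probabilities over variant classes (must
#'   sum to 1).
#' @param snv_class_probs named probabilities over the six
#'   pyrimidine-reference substitution classes (must sum to 1;
#'   C>T-dominant by default).
#' @param seed integer RNG seed or `NULL`.
#' @return object of class `cohort_sim_config` (with the calibrated
#'   conditional probabilities in `$cond_probs`).
#' @export
cohort_sim_config <- function(n_samples = 493,
                              gene_freqs = default_gene_freqs(),
                              detection_rate = 464 / 493,
                              extra_rate = 0.08,
                              max_variants = 33,
                              vaf_meanlog = log(0.004), vaf_sdlog = 1.1,
                              vaf_min = 5e-4, vaf_max = 0.3,
                              class_probs = c(missense = 0.62,
                                              stopgain = 0.10,
                                              frameshift_indel = 0.12,
                                              nonframeshift_indel = 0.06,
                                              splice_site = 0.05,
                                              promoter = 0.05),
                              snv_class_probs = c("C>A" = 0.08,
                                                  "C>G" = 0.06,
                                                  "C>T" = 0.40,
                                                  "T>A" = 0.09,
                                                  "T>C" = 0.27,
                                                  "T>G" = 0.10),
                              seed = NULL) {
  assert_that(length(gene_freqs) > 0 && !is.null(names(gene_freqs)),
              "gene_freqs must be a non-empty named vector")
  assert_that(all(gene_freqs >= 0 & gene_freqs <= 1),
              "gene_freqs must lie in [0,1]")
  assert_that(detection_rate >= 0 && detection_rate <= 1,
              "detection_rate must lie in [0,1]")
  assert_that(all(gene_freqs <= detection_rate + 1e-12),
              "no gene_freqs entry can exceed detection_rate")
  assert_that(abs(sum(class_probs) - 1) < 1e-9,
              "class_probs must sum to 1")
  assert_that(all(names(class_probs) %in% ALL_CLASSES),
              "unknown variant class in class_probs")
  assert_that(abs(sum(snv_class_probs) - 1) < 1e-9,
              "snv_class_probs must sum to 1")
  assert_that(setequal(names(snv_class_probs), SNV_CLASSES),
              "snv_class_probs must cover the six SNV classes")
  assert_that(vaf_min > 0 && vaf_max < 1 && vaf_min < vaf_max,
              "VAF truncation bounds must satisfy 0 < min < max < 1")
  cfg <- list(n_samples = n_samples, gene_freqs = gene_freqs,
              detection_rate = detection_rate, extra_rate = extra_rate,
              max_variants = max_variants, vaf_meanlog = vaf_meanlog,
              vaf_sdlog = vaf_sdlog, vaf_min = vaf_min,
              vaf_max = vaf_max, class_probs = class_probs,
              snv_class_probs = snv_class_probs, seed = seed)
  cfg$cond_probs <- calibrate_cond_probs(gene_freqs, detection_rate)
  structure(cfg, class = "cohort_sim_config")
}

# Solve c_g = p_g * (1 - P0) / pi with P0 = prod(1 - c), the fixed point
# making marginal gene frequencies exact under zero-inflation plus
# conditioning of shedding samples on >= 1 mutation.
calibrate_cond_probs <- function(p, detection_rate) {
  if (detection_rate == 0) return(p * 0)
  cc <- pmin(p / detection_rate, 1)
  for (i in 1:60) {
    p0 <- prod(1 - cc)
    cc_new <- pmin(p * (1 - p0) / detection_rate, 1)
    if (max(abs(cc_new - cc)) < 1e-12) { cc <- cc_new; break }
    cc <- cc_new
  }
  assert_that(all(cc <= 1),
              "gene_freqs incompatible with detection_rate (freq > rate)")
  cc
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

# draw a ref>alt base pair realizing the given collapsed SNV class,
# presented on either strand with equal probability
draw_ref_alt <- function(n, snv_class_probs) {
  cls <- sample(names(snv_class_probs), n, replace = TRUE,
                prob = snv_class_probs)
  ref <- substr(cls, 1, 1); alt <- substr(cls, 3, 3)
  flip <- stats::runif(n) < 0.5
  ref[flip] <- COMPLEMENT[ref[flip]]
  alt[flip] <- COMPLEMENT[alt[flip]]
  list(ref = ref, alt = alt)
}

synth_hgvs <- function(class, snv_class_probs) {
  n <- length(class)
  pos <- sample(20:1200, n, replace = TRUE)
  ra <- draw_ref_alt(n, snv_class_probs)
  aa <- sample(AA1, n, replace = TRUE)
  aa2 <- sample(AA1, n, replace = TRUE)
  cdot <- character(n); pdot <- character(n); type <- character(n)
  for (i in seq_len(n)) {
    switch(class[i],
      missense = {
        while (aa2[i] == aa[i]) aa2[i] <- sample(AA1, 1)
        cdot[i] <- sprintf("c.%d%s>%s", 3 * pos[i], ra$ref[i], ra$alt[i])
        pdot[i] <- sprintf("p.%s%d%s", aa[i], pos[i], aa2[i])
        type[i] <- "Substitution"
      },
      stopgain = {
        cdot[i] <- sprintf("c.%d%s>%s", 3 * pos[i], ra$ref[i], ra$alt[i])
        pdot[i] <- sprintf("p.%s%d*", aa[i], pos[i])
        type[i] <- "Substitution"
      },
      frameshift_indel = {
        cdot[i] <- sprintf("c.%ddel", 3 * pos[i])
        pdot[i] <- sprintf("p.%s%d%sfs*%d", aa[i], pos[i], aa2[i],
                           sample(2:40, 1))
        type[i] <- "Deletion"
      },
      nonframeshift_indel = {
        cdot[i] <- sprintf("c.%d_%ddel", 3 * pos[i] - 2, 3 * pos[i])
        pdot[i] <- sprintf("p.%s%ddel", aa[i], pos[i])
        type[i] <- "Deletion"
      },
      splice_site = {
        cdot[i] <- sprintf("c.%d%s%d%s>%s", 3 * pos[i],
                           sample(c("-", "+"), 1), sample(1:2, 1),
                           ra$ref[i], ra$alt[i])
        pdot[i] <- ""
        type[i] <- "Substitution"
      },
      promoter = {
        cdot[i] <- sprintf("c.-%d%s>%s", sample(30:300, 1),
                           ra$ref[i], ra$alt[i])
        pdot[i] <- ""
        type[i] <- "Substitution"
      },
      {
        cdot[i] <- sprintf("c.%d%s>%s", 3 * pos[i], ra$ref[i], ra$alt[i])
        pdot[i] <- sprintf("p.%s%d%s", aa[i], pos[i], aa[i])
        type[i] <- "Substitution"
      })
  }
  list(cdot = cdot, pdot = pdot, type = type)
}

#' Generate a synthetic ctDNA cohort variant table
#'
#' See [cohort_sim_config()] for the generative model. Identical seed
#' and configuration give byte-identical tables.
#'
#' @param config a `cohort_sim_config`.
#' @param n_samples,seed optional overrides of the config values.
#' @return a `ctdna_cohort`; samples are labelled `S0001`... with
#'   cohort label `synthetic`, and `covered_genes` maps the `custom`
#'   panel to the configured gene universe.
#' @export
generate_cohort <- function(config, n_samples = NULL, seed = NULL) {
  assert_that(inherits(config, "cohort_sim_config"),
              "config must come from cohort_sim_config()")
  n <- n_samples %||% config$n_samples
  seed <- seed %||% config$seed
  with_seed(seed, {
    genes <- names(config$gene_freqs)
    G <- length(genes)
    cc <- config$cond_probs
    shed <- stats::runif(n) < config$detection_rate
    ids <- sprintf("S%04d", seq_len(n))
    rows <- list()
    if (any(shed)) {
      ns <- sum(shed)
      hits <- matrix(stats::runif(ns * G), ns, G) <
        matrix(cc, ns, G, byrow = TRUE)
      empty <- which(rowSums(hits) == 0)
      while (length(empty)) {
        hits[empty, ] <- matrix(stats::runif(length(empty) * G),
                                length(empty), G) <
          matrix(cc, length(empty), G, byrow = TRUE)
        empty <- empty[rowSums(hits[empty, , drop = FALSE]) == 0]
      }
      shed_ids <- ids[shed]
      for (i in seq_len(ns)) {
        g_hit <- genes[hits[i, ]]
        mult <- 1L + stats::rgeom(length(g_hit), 1 - config$extra_rate)
        # cap the sample burden, trimming extras from the end
        while (sum(mult) > config$max_variants && any(mult > 1))
          mult[which.max(mult)] <- mult[which.max(mult)] - 1L
        rows[[i]] <- data.frame(sample_id = shed_ids[i],
                                gene = rep(g_hit, mult),
                                stringsAsFactors = FALSE)
      }
    }
    v <- if (length(rows)) do.call(rbind, rows) else
      data.frame(sample_id = character(), gene = character())
    nv <- nrow(v)
    if (nv) {
      v$chrom <- paste0("chr", 1 + (match(v$gene, genes) %% 22))
      v$exon_label <- sprintf("Exon%d", sample(1:30, nv, replace = TRUE))
      cls <- sample(names(config$class_probs), nv, replace = TRUE,
                    prob = config$class_probs)
      hg <- synth_hgvs(cls, config$snv_class_probs)
      v$cdot <- hg$cdot
      v$pdot <- hg$pdot
      v$exon_label[cls %in% NONCODING_HOTSPOT_CLASSES] <- ""
      v$vaf <- round(rtrunc_lnorm(nv, config$vaf_meanlog,
                                  config$vaf_sdlog, config$vaf_min,
                                  config$vaf_max), 6)
      v$variant_type <- hg$type
      v$variant_class <- cls
    }
    samples <- data.frame(sample_id = ids, patient_id = ids,
                          cohort_label = "synthetic",
                          panel_id = "custom",
                          collection_day = NA_integer_,
                          stringsAsFactors = FALSE)
    cohort_variant_table(v, samples = samples,
                         covered_genes = list(custom = genes))
  })
}

#' Configuration for the synthetic surgical (MRD outcome) cohort
#'
#' Emulates a post-resection cohort with MRD-linked relapse hazards:
#' MRD status is Bernoulli(`mrd_prevalence`); relapse times are
#' exponential with rate `baseline_hazard` for MRD-negative and
#' `baseline_hazard * hazard_ratio` for MRD-positive patients, with
#' administrative censoring at `followup_horizon` months.
#'
#' @param n_patients default 20.
#' @param mrd_prevalence default 0.30.
#' @param baseline_hazard events/month among MRD-negative patients;
#'   default 0.011 (about a 15% two-year relapse risk).
#' @param hazard_ratio relapse hazard ratio of MRD-positive vs
#'   negative; default 13.
#' @param followup_horizon censoring horizon in months; default 24.
#' @param early_relapse_window months defining early relapse; default
#'   24.
#' @param seed RNG seed or `NULL`.
#' @return object of class `surgical_sim_config`.
#' @export
surgical_sim_config <- function(n_patients = 20, mrd_prevalence = 0.30,
                                baseline_hazard = 0.011,
                                hazard_ratio = 13,
                                followup_horizon = 24,
                                early_relapse_window = 24,
                                seed = NULL) {
  assert_that(mrd_prevalence >= 0 && mrd_prevalence <= 1,
              "mrd_prevalence must lie in [0,1]")
  assert_that(baseline_hazard >= 0 && hazard_ratio >= 0,
              "rates must be >= 0")
  assert_that(followup_horizon > 0, "followup_horizon must be > 0")
  structure(list(n_patients = n_patients,
                 mrd_prevalence = mrd_prevalence,
                 baseline_hazard = baseline_hazard,
                 hazard_ratio = hazard_ratio,
                 followup_horizon = followup_horizon,
                 early_relapse_window = early_relapse_window,
                 seed = seed),
            class = "surgical_sim_config")
}

#' Generate a synthetic surgical cohort with MRD-linked outcomes
#'
#' MRD-positive patients receive one to three variants in monitoring
#' panel genes; MRD-negative patients receive zero to two variants in
#' non-panel genes only, so that the one-or-more-panel-mutation rule
#' recovers the simulated status exactly.
#'
#' @param config a `surgical_sim_config`.
#' @param panel monitoring panel used to place the positive patients'
#'   variants; default [default_hcc_panel()].
#' @param seed optional override of the config seed.
#' @return list with `cohort` (a `ctdna_cohort`) and `survival`
#'   (data.frame `patient_id`, `time_months`, `event`, `mrd_status`,
#'   `early_relapse`).
#' @export
generate_surgical_cohort <- function(config, panel = default_hcc_panel(),
                                     seed = NULL) {
  assert_that(inherits(config, "surgical_sim_config"),
              "config must come from surgical_sim_config()")
  seed <- seed %||% config$seed
  panel_genes <- if (inherits(panel, "mrd_panel")) panel$genes else panel
  off_panel <- setdiff(names(default_gene_freqs()), panel_genes)
  with_seed(seed, {
    n <- config$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    status <- stats::runif(n) < config$mrd_prevalence
    rate <- config$baseline_hazard *
      ifelse(status, config$hazard_ratio, 1)
    tt <- ifelse(rate > 0, stats::rexp(n, pmax(rate, 1e-12)), Inf)
    event <- as.integer(tt <= config$followup_horizon)
    time <- pmin(tt, config$followup_horizon)
    rows <- list()
    for (i in seq_len(n)) {
      if (status[i]) {
        k <- sample(1:3, 1)
        gs <- sample(panel_genes, k)
      } else {
        k <- sample(0:2, 1)
        gs <- if (k) sample(off_panel, k) else character()
      }
      if (!length(gs)) next
      hg <- synth_hgvs(rep("missense", length(gs)),
                       c("C>A" = 0.08, "C>G" = 0.06, "C>T" = 0.40,
                         "T>A" = 0.09, "T>C" = 0.27, "T>G" = 0.10))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[i], gene = gs, chrom = "chr1",
        exon_label = "", cdot = hg$cdot, pdot = hg$pdot,
        vaf = round(rtrunc_lnorm(length(gs), log(0.004), 1, 5e-4, 0.3), 6),
        variant_type = hg$type, stringsAsFactors = FALSE)
    }
    v <- if (length(rows)) do.call(rbind, rows) else NULL
    samples <- data.frame(sample_id = ids, patient_id = ids,
                          cohort_label = "synthetic",
                          panel_id = "custom",
                          collection_day = 7L, stringsAsFactors = FALSE)
    surv <- data.frame(
      patient_id = ids, time_months = time, event = event,
      mrd_status = ifelse(status, "positive", "negative"),
      early_relapse = event == 1 & time <= config$early_relapse_window,
      stringsAsFactors = FALSE)
    list(cohort = cohort_variant_table(v, samples = samples),
         survival = surv)
  })
}

#' Configuration for simulated pileup counts
#'
#' @param n_loci number of loci; default 2000.
#' @param depth_mean mean sequencing depth; default 5161 (the assay's
#'   average effective depth).
#' @param depth_dispersion negative-binomial size of the depth
#'   distribution; default 20.
#' @param background_error_rate per-base background error rate, scalar
#'   or length `n_loci`; default 1e-3.
#' @param true_variant_fraction fraction of loci carrying a true
#'   variant; default 0.1.
#' @param true_vaf_meanlog,true_vaf_sdlog log-normal parameters of true
#'   VAFs (defaults put the median at 0.005); truncated to
#'   \[1e-3, 0.3\].
#' @param seed RNG seed or `NULL`.
#' @return object of class `pileup_sim_config`.
#' @export
pileup_sim_config <- function(n_loci = 2000, depth_mean = 5161,
                              depth_dispersion = 20,
                              background_error_rate = 1e-3,
                              true_variant_fraction = 0.1,
                              true_vaf_meanlog = log(0.005),
                              true_vaf_sdlog = 0.4,
                              seed = NULL) {
  assert_that(depth_mean > 0, "depth_mean must be > 0")
  assert_that(all(background_error_rate >= 0 &
                    background_error_rate < 1),
              "background_error_rate must lie in [0,1)")
  assert_that(true_variant_fraction >= 0 && true_variant_fraction <= 1,
              "true_variant_fraction must lie in [0,1]")
  structure(list(n_loci = n_loci, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 background_error_rate = background_error_rate,
                 true_variant_fraction = true_variant_fraction,
                 true_vaf_meanlog = true_vaf_meanlog,
                 true_vaf_sdlog = true_vaf_sdlog, seed = seed),
            class = "pileup_sim_config")
}

#' Generate simulated per-locus read counts
#'
#' Depth per locus is negative-binomial around `depth_mean`; alt reads
#' are binomial with the background error rate at null loci and with
#' the drawn true VAF at variant loci. Ground-truth labels are carried
#' for benchmarking the locus caller.
#'
#' @param config a `pileup_sim_config`.
#' @param seed optional override of the config seed.
#' @return data.frame (`locus_id`, `depth`, `alt_count`,
#'   `background_error_rate`, `truth`, `true_vaf`).
#' @export
generate_pileups <- function(config, seed = NULL) {
  assert_that(inherits(config, "pileup_sim_config"),
              "config must come from pileup_sim_config()")
  seed <- seed %||% config$seed
  with_seed(seed, {
    n <- config$n_loci
    depth <- stats::rnbinom(n, size = config$depth_dispersion,
                            mu = config$depth_mean)
    depth <- pmax(depth, 1L)
    err <- rep_len(config$background_error_rate, n)
    truth <- stats::runif(n) < config$true_variant_fraction
    vaf <- rep(NA_real_, n)
    if (any(truth))
      vaf[truth] <- rtrunc_lnorm(sum(truth), config$true_vaf_meanlog,
                                 config$true_vaf_sdlog, 1e-3, 0.3)
    p_alt <- ifelse(truth, vaf, err)
    alt <- stats::rbinom(n, depth, p_alt)
    data.frame(locus_id = sprintf("L%05d", seq_len(n)), depth = depth,
               alt_count = alt, background_error_rate = err,
               truth = truth, true_vaf = vaf, stringsAsFactors = FALSE)
  })
}
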