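#' Per-gene mutation frequencies across a cohort
#'
#' A sample counts once per gene regardless of how many variants it
#' carries there. The denominator is, by default, the number of samples
#' whose sequencing panel covers the gene (`denominator = "per_gene"`),
#' which avoids deflating frequencies of genes exclusive to one of two
#' merged panels; `denominator = "cohort"` uses the full cohort size for
#' every gene.
#'
#' @param cohort a `ctdna_cohort` (already retention-filtered).
#' @param denominator `"per_gene"` or `"cohort"`.
#' @return data.frame (`gene`, `n_mutated`, `n_eligible`, `frequency`)
#'   sorted by decreasing frequency, ties broken alphabetically.
#' @export
gene_mutation_frequency <- function(cohort,
                                    denominator = c("per_gene", "cohort")) {
  denominator <- match.arg(denominator)
  assert_that(nrow(cohort$samples) > 0, "empty cohort")
  v <- cohort$variants
  hits <- unique(v[, c("sample_id", "gene")])
  genes <- sort(unique(hits$gene))
  n_mut <- vapply(genes, function(g)
    length(unique(hits$sample_id[hits$gene == g])), 1L)
  n_total <- nrow(cohort$samples)
  if (denominator == "cohort" || is.null(cohort$covered_genes)) {
    n_elig <- rep(n_total, length(genes))
  } else {
    pan <- cohort$samples$panel_id
    n_elig <- vapply(genes, function(g) {
      covers <- vapply(unique(pan), function(p) {
        cov <- cohort$covered_genes[[p]]
        is.null(cov) || g %in% cov
      }, logical(1))
      sum(pan %in% unique(pan)[covers])
    }, 1L)
  }
  out <- data.frame(gene = genes, n_mutated = n_mut, n_eligible = n_elig,
                    frequency = n_mut / n_elig,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of samples with at least one retained variant
#'
#' @param cohort a `ctdna_cohort`.
#' @return fraction in \[0,1\].
#' @export
detection_rate <- function(cohort) {
  assert_that(nrow(cohort$samples) > 0, "empty cohort")
  length(unique(cohort$variants$sample_id)) / nrow(cohort$samples)
}

#' Counts of variants by class
#'
#' @param cohort a `ctdna_cohort`.
#' @return named integer vector over all variant classes (zeros kept).
#' @export
variant_class_summary <- function(cohort) {
  tab <- table(factor(cohort$variants$variant_class, levels = ALL_CLASSES))
  stats::setNames(as.integer(tab), names(tab))
}

SNV_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Base-substitution (SNV class) spectrum
#'
#' Parses `ref>alt` from the coding change of substitution variants and
#' collapses purine-reference changes onto their pyrimidine reverse
#' complement (`G>A` → `C>T`, etc.), yielding the conventional six
#' classes. Non-substitutions and unparsable coding changes are ignored.
#'
#' @param cohort a `ctdna_cohort`.
#' @return named integer vector over `C>A, C>G, C>T, T>A, T>C, T>G`.
#' @export
snv_class_summary <- function(cohort) {
  v <- cohort$variants
  v <- v[v$variant_type == "Substitution", , drop = FALSE]
  cls <- snv_class_of(v$cdot)
  tab <- table(factor(cls[!is.na(cls)], levels = SNV_CLASSES))
  stats::setNames(as.integer(tab), names(tab))
}

# "c.607G>A" -> "C>T"; NA when no single-base ref>alt is present
snv_class_of <- function(cdot) {
  m <- regmatches(cdot, regexec("([ACGT])>([ACGT])$", as.character(cdot)))
  vapply(m, function(x) {
    if (length(x) != 3) return(NA_character_)
    ref <- x[2]; alt <- x[3]
    if (ref %in% c("G", "A")) {
      ref <- COMPLEMENT[[ref]]; alt <- COMPLEMENT[[alt]]
    }
    paste0(ref, ">", alt)
  }, character(1))
}

#' Variant burden per mutation-bearing sample
#'
#' @param cohort a `ctdna_cohort`.
#' @return list with `counts` (named integer vector over samples with at
#'   least one variant), `median`, `min`, `max` (all `NA` when no sample
#'   carries a variant).
#' @export
variants_per_sample <- function(cohort) {
  v <- cohort$variants
  if (nrow(v) == 0)
    return(list(counts = integer(), median = NA_real_,
                min = NA_integer_, max = NA_integer_))
  tab <- table(v$sample_id)
  counts <- stats::setNames(as.integer(tab), names(tab))
  list(counts = counts, median = stats::median(counts),
       min = min(counts), max = max(counts))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return named list of gene symbol vectors.
#' @export
read_gene_sets <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lapply(fgsea::gmtPathways(path), normalize_gene)
}

#' Pathway mutation burden
#'
#' A sample affects a pathway when at least one retained variant falls
#' in a member gene. Member genes never observed in the cohort are
#' counted per pathway in `n_unknown_genes` (with one warning overall)
#' but do not otherwise contribute.
#'
#' @param cohort a `ctdna_cohort`.
#' @param pathway_sets named list mapping pathway name to gene vector
#'   (see [read_gene_sets()]).
#' @return data.frame (`pathway`, `n_mutated_genes`,
#'   `n_affected_samples`, `n_unknown_genes`).
#' @export
pathway_summary <- function(cohort, pathway_sets) {
  v <- cohort$variants
  seen <- unique(v$gene)
  rows <- lapply(names(pathway_sets), function(pw) {
    gs <- normalize_gene(pathway_sets[[pw]])
    hit <- v[v$gene %in% gs, , drop = FALSE]
    data.frame(pathway = pw,
               n_mutated_genes = length(unique(hit$gene)),
               n_affected_samples = length(unique(hit$sample_id)),
               n_unknown_genes = sum(!gs %in% seen),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway = character(), n_mutated_genes = integer(),
               n_affected_samples = integer(), n_unknown_genes = integer())
  if (sum(out$n_unknown_genes) > 0)
    warning(sum(out$n_unknown_genes),
            " pathway member gene(s) never observed in the cohort",
            call. = FALSE)
  out
}

#' Pairwise co-occurrence / mutual exclusivity of mutated genes
#'
#' For each pair among the `top_n` most frequently mutated genes, builds
#' the 2x2 sample presence/absence table and applies the two-sided
#' Fisher exact test. A pair is labelled `co_occurring` when `p < alpha`
#' with sample odds ratio > 1, `mutually_exclusive` when `p < alpha`
#' with odds ratio < 1, otherwise `none`. Benjamini-Hochberg adjusted
#' p-values are reported alongside the raw ones; labelling uses the raw
#' p, matching common practice for this analysis. A mid-p variant
#' (`midp = TRUE`) reduces the slight conservatism of the exact test but
#' is not the default.
#'
#' @param cohort a `ctdna_cohort`.
#' @param top_n number of top-frequency genes to cross (ties broken
#'   alphabetically); default 25.
#' @param alpha significance level for labelling; default 0.05.
#' @param midp logical, use the mid-p two-sided exact p-value.
#' @return data.frame, one row per unordered pair: `gene_a`, `gene_b`,
#'   `n_both`, `n_a_only`, `n_b_only`, `n_neither`, `odds_ratio`
#'   (sample OR, `Inf`/0 allowed), `p_value`, `adjusted_p`, `label`.
#' @export
somatic_interactions <- function(cohort, top_n = 25, alpha = 0.05,
                                 midp = FALSE) {
  freq <- gene_mutation_frequency(cohort, denominator = "cohort")
  assert_that(nrow(freq) >= 2, "need at least 2 mutated genes")
  genes <- utils::head(freq$gene, top_n)
  ids <- cohort$samples$sample_id
  n <- length(ids)
  pres <- sapply(genes, function(g)
    ids %in% cohort$variants$sample_id[cohort$variants$gene == g])
  pres <- matrix(pres, nrow = n, dimnames = list(NULL, genes))
  pairs <- utils::combn(genes, 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- pres[, pr[1]]; b <- pres[, pr[2]]
    n11 <- sum(a & b); n10 <- sum(a & !b)
    n01 <- sum(!a & b); n00 <- sum(!a & !b)
    p <- fisher_p_2x2(n11, n10, n01, n00, midp = midp)
    or <- (n11 * n00) / (n10 * n01) # sample OR; 0/0 -> NaN kept explicit
    data.frame(gene_a = pr[1], gene_b = pr[2], n_both = n11,
               n_a_only = n10, n_b_only = n01, n_neither = n00,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$label <- "none"
  sig <- out$p_value < alpha
  out$label[sig & out$odds_ratio > 1] <- "co_occurring"
  out$label[sig & out$odds_ratio < 1] <- "mutually_exclusive"
  out
}

# two-sided Fisher exact p for a 2x2 table, optional mid-p correction
fisher_p_2x2 <- function(n11, n10, n01, n00, midp = FALSE) {
  tb <- matrix(c(n11, n01, n10, n00), 2)
  p <- stats::fisher.test(tb)$p.value
  if (midp) {
    m <- n11 + n10; nn <- n01 + n00; k <- n11 + n01
    p <- p - 0.5 * stats::dhyper(n11, m, nn, k)
  }
  min(1, p)
}

#' Positional-clustering driver score
#'
#' A deliberately simple hotspot-clustering score over protein residue
#' positions, in the spirit of positional-clustering driver detection:
#' for each gene with at least `min_mutations` variants carrying a
#' parsable protein position, residues observed mutated at least twice
#' seed clusters, which then absorb any mutated residue within `gap`
#' residues of a cluster member (transitively). The clustering score is
#' the fraction of the gene's mutations inside clusters, and z-scores
#' are taken across all qualifying genes. No synonymous background model
#' is used (the upstream retention filter removes synonymous calls).
#'
#' @param cohort a `ctdna_cohort`.
#' @param min_mutations minimum parsable mutations for a gene to
#'   qualify; default 5.
#' @param gap maximum residue distance absorbed into a cluster; default
#'   5.
#' @return data.frame sorted by decreasing z-score: `gene`,
#'   `n_mutations`, `n_clustered`, `n_clusters`, `clustering_score`,
#'   `z_score`; the per-gene cluster tables (`start_residue`,
#'   `end_residue`, `n`) are in the `clusters` attribute. Empty (zero
#'   rows) when no gene qualifies.
#' @export
driver_clustering <- function(cohort, min_mutations = 5, gap = 5) {
  v <- cohort$variants
  pp <- parse_protein_change(v$pdot)
  v <- v[pp$ok, , drop = FALSE]
  pos <- pp$position[pp$ok]
  empty <- data.frame(gene = character(), n_mutations = integer(),
                      n_clustered = integer(), n_clusters = integer(),
                      clustering_score = numeric(), z_score = numeric())
  if (nrow(v) == 0) return(empty)
  genes <- names(which(table(v$gene) >= min_mutations))
  if (!length(genes)) return(empty)
  clusters <- list()
  rows <- lapply(sort(genes), function(g) {
    res <- pos[v$gene == g]
    cl <- residue_clusters(res, gap = gap)
    clusters[[g]] <<- cl
    n_in <- if (nrow(cl)) sum(cl$n) else 0L
    data.frame(gene = g, n_mutations = length(res), n_clustered = n_in,
               n_clusters = nrow(cl),
               clustering_score = n_in / length(res),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  s <- out$clustering_score
  out$z_score <- if (length(s) > 1 && stats::sd(s) > 0)
    (s - mean(s)) / stats::sd(s) else 0
  out <- out[order(-out$z_score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clusters") <- clusters
  out
}

# seed-and-extend clustering of mutated residues: seeds are residues hit
# >= 2 times; a cluster absorbs mutated residues within `gap` of any
# member, transitively. Returns per-cluster start/end/n (mutation count).
residue_clusters <- function(residues, gap = 5) {
  tab <- table(residues)
  ures <- as.integer(names(tab))
  cnt <- as.integer(tab)
  o <- order(ures); ures <- ures[o]; cnt <- cnt[o]
  # transitive chaining: consecutive unique residues within `gap` form a
  # chain; a chain is a cluster iff it contains a seed (residue with >=2)
  brk <- c(TRUE, diff(ures) > gap)
  chain <- cumsum(brk)
  keep <- vapply(split(cnt, chain), function(x) any(x >= 2), logical(1))
  out <- lapply(which(keep), function(ch) {
    idx <- chain == ch
    data.frame(start_residue = min(ures[idx]), end_residue = max(ures[idx]),
               n = sum(cnt[idx]))
  })
  if (!length(out))
    return(data.frame(start_residue = integer(), end_residue = integer(),
                      n = integer()))
  do.call(rbind, out)
}
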