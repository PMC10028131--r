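#' Call MRD status for one plasma sample
#'
#' A sample is MRD-positive when at least one retained variant falls in
#' a monitoring-panel gene, MRD-negative otherwise. Only retained
#' classes count: a panel-gene variant of class `other`, `synonymous`,
#' or (when `keep_noncoding_hotspots = FALSE` upstream) a non-coding
#' class does not trigger positivity, because the retention rule gates
#' all downstream analysis. There is no VAF floor by default
#' (`min_vaf = 0`); post-operative supporting variants down to VAF
#' ~0.002 are legitimate calls at the assay's depth.
#'
#' @param sample_variants data.frame of the sample's variants (columns
#'   as in a `ctdna_cohort`'s `variants` slot); may have zero rows.
#' @param panel an `mrd_panel` or character vector of panel genes.
#' @param min_vaf optional minimum VAF for a variant to support
#'   positivity; default 0.
#' @param sample_id identifier for the result (defaults to the one in
#'   `sample_variants`, or `NA`).
#' @return object of class `mrd_call`: `sample_id`, `status`
#'   (`"positive"`/`"negative"`), `supporting_variants` (data.frame
#'   restricted to panel genes), `max_vaf` (`NA` when negative),
#'   `n_panel_genes_hit`.
#' @examples
#' panel <- default_hcc_panel()
#' v <- data.frame(sample_id = "79060", gene = "TP53", cdot = "c.607G>A",
#'                 pdot = "p.V203M", vaf = 0.002152,
#'                 variant_type = "Substitution")
#' call_mrd(v, panel)
#' @export
call_mrd <- function(sample_variants, panel, min_vaf = 0,
                     sample_id = NULL) {
  genes <- if (inherits(panel, "mrd_panel")) panel$genes else
    normalize_gene(panel)
  if (is.null(sample_variants) || nrow(sample_variants) == 0) {
    sv <- empty_variants()
  } else {
    sv <- sample_variants
    if (is.null(sv[["variant_class"]]))
      sv$variant_class <- classify_variant(sv$cdot, sv[["pdot"]] %||% "")
    sv$gene <- normalize_gene(sv$gene)
    keep <- sv$gene %in% genes &
      sv$variant_class %in% c(RETAINED_CLASSES, NONCODING_HOTSPOT_CLASSES) &
      sv$vaf >= min_vaf
    sv <- sv[keep, , drop = FALSE]
    rownames(sv) <- NULL
  }
  if (is.null(sample_id))
    sample_id <- if (nrow(sv)) sv$sample_id[1]
      else if (!is.null(sample_variants) && nrow(sample_variants))
        sample_variants$sample_id[1] else NA_character_
  positive <- nrow(sv) > 0
  structure(list(sample_id = sample_id,
                 status = if (positive) "positive" else "negative",
                 supporting_variants = sv,
                 max_vaf = if (positive) max(sv$vaf) else NA_real_,
                 n_panel_genes_hit = length(unique(sv$gene))),
            class = "mrd_call")
}

#' @export
print.mrd_call <- function(x, ...) {
  cat("MRD call for sample ", x$sample_id, ": ", toupper(x$status), sep = "")
  if (x$status == "positive")
    cat(sprintf(" (%d panel gene%s, max VAF %.6f)",
                x$n_panel_genes_hit,
                if (x$n_panel_genes_hit > 1) "s" else "", x$max_vaf))
  cat("\n")
  invisible(x)
}

#' Call MRD status across a cohort
#'
#' Applies [call_mrd()] per sample (including samples with no variants,
#' which are negative) and tabulates positives and negatives.
#'
#' @param cohort a `ctdna_cohort` (retention-filtered variants).
#' @param panel an `mrd_panel` or character vector of panel genes.
#' @param min_vaf forwarded to [call_mrd()].
#' @return list with `calls` (data.frame `sample_id`, `status`,
#'   `n_panel_genes_hit`, `n_supporting`, `max_vaf`), `results` (list of
#'   `mrd_call`), `n_positive`, `n_negative`.
#' @export
cohort_mrd <- function(cohort, panel, min_vaf = 0) {
  ids <- cohort$samples$sample_id
  results <- lapply(ids, function(s)
    call_mrd(cohort$variants[cohort$variants$sample_id == s, , drop = FALSE],
             panel, min_vaf = min_vaf, sample_id = s))
  calls <- data.frame(
    sample_id = ids,
    status = vapply(results, `[[`, "", "status"),
    n_panel_genes_hit = vapply(results, `[[`, 1L, "n_panel_genes_hit"),
    n_supporting = vapply(results, function(r) nrow(r$supporting_variants),
                          1L),
    max_vaf = vapply(results, `[[`, 1, "max_vaf"),
    stringsAsFactors = FALSE)
  list(calls = calls, results = stats::setNames(results, ids),
       n_positive = sum(calls$status == "positive"),
       n_negative = sum(calls$status == "negative"))
}
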