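#' Variant classes retained for MRD analysis
#'
#' Coding classes kept by [retention_filter()]: missense, stopgain,
#' frameshift indel and non-frameshift indel. Promoter and splice-site
#' variants form the optional non-coding hotspot extension.
#'
#' @format Character vectors of class labels.
#' @name variant_classes
NULL

#' @rdname variant_classes
#' @export
RETAINED_CLASSES <- c("missense", "stopgain", "frameshift_indel",
                      "nonframeshift_indel")

#' @rdname variant_classes
#' @export
NONCODING_HOTSPOT_CLASSES <- c("promoter", "splice_site")

ALL_CLASSES <- c(RETAINED_CLASSES, NONCODING_HOTSPOT_CLASSES,
                 "synonymous", "other")

VARIANT_TYPES <- c("Substitution", "Deletion", "Insertion")

# the running text of some reports uses non-HUGO spellings; normalized here
GENE_ALIASES <- c(RMB10 = "RBM10")

#' Normalize gene symbols
#'
#' Trims whitespace and maps known non-standard spellings (e.g. `RMB10`)
#' to their HUGO symbol. Matching elsewhere in the package is
#' case-sensitive and exact after this normalization.
#'
#' @param genes character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
normalize_gene <- function(genes) {
  g <- trimws(as.character(genes))
  hit <- g %in% names(GENE_ALIASES)
  g[hit] <- unname(GENE_ALIASES[g[hit]])
  g
}

variant_columns <- c("sample_id", "gene", "chrom", "exon_label",
                     "cdot", "pdot", "vaf", "variant_type", "variant_class")

empty_variants <- function() {
  data.frame(sample_id = character(), gene = character(),
             chrom = character(), exon_label = character(),
             cdot = character(), pdot = character(),
             vaf = numeric(), variant_type = character(),
             variant_class = character(), stringsAsFactors = FALSE)
}

#' Construct a cohort variant table
#'
#' The central container of the package: per-sample annotated somatic
#' variant calls plus sample metadata and, optionally, the gene sets
#' covered by each sequencing panel (used as frequency denominators).
#'
#' @param variants data.frame with columns `sample_id`, `gene`, `cdot`,
#'   `vaf`, `variant_type`; optional `chrom`, `exon_label`, `pdot`,
#'   `variant_class`. Missing `variant_class` values are derived with
#'   [classify_variant()].
#' @param samples optional data.frame with columns `sample_id` and
#'   optionally `patient_id`, `cohort_label`, `panel_id`,
#'   `collection_day`. Defaults to one row per distinct variant
#'   `sample_id`. Samples without variants are legal and matter for
#'   frequency denominators.
#' @param covered_genes optional named list mapping `panel_id` to the
#'   character vector of genes that panel covers. A panel absent from the
#'   list is taken to cover every gene.
#' @return object of class `ctdna_cohort` with elements `variants`,
#'   `samples`, `covered_genes`.
#' @examples
#' v <- data.frame(sample_id = "s1", gene = "TP53", cdot = "c.747G>T",
#'                 pdot = "p.R249S", vaf = 0.01, variant_type = "Substitution")
#' cohort_variant_table(v)
#' @export
cohort_variant_table <- function(variants, samples = NULL,
                                 covered_genes = NULL) {
  if (is.null(variants) || nrow(variants) == 0) {
    variants <- empty_variants()
  } else {
    need <- c("sample_id", "gene", "cdot", "vaf", "variant_type")
    miss <- setdiff(need, names(variants))
    if (length(miss))
      stop_mrd("variant table is missing mandatory column(s): ",
               paste(miss, collapse = ", "))
    for (col in c("chrom", "exon_label", "pdot"))
      if (is.null(variants[[col]])) variants[[col]] <- ""
    variants$sample_id <- as.character(variants$sample_id)
    variants$gene <- normalize_gene(variants$gene)
    variants$chrom <- as.character(variants$chrom)
    variants$exon_label <- as.character(variants$exon_label)
    variants$cdot <- trimws(as.character(variants$cdot))
    variants$pdot <- trimws(as.character(variants$pdot))
    variants$pdot[is.na(variants$pdot)] <- ""
    variants$vaf <- as.numeric(variants$vaf)
    variants$variant_type <- as.character(variants$variant_type)
    if (is.null(variants[["variant_class"]]))
      variants$variant_class <- classify_variant(variants$cdot, variants$pdot)
    variants <- variants[, variant_columns]
    rownames(variants) <- NULL
    bad <- validate_variant_rows(variants)
    if (any(nzchar(bad)))
      stop_mrd("invalid variant row(s): ",
               paste(which(nzchar(bad)), bad[nzchar(bad)],
                     sep = ": ", collapse = "; "))
  }
  if (is.null(samples)) {
    ids <- unique(variants$sample_id)
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  assert_that("sample_id" %in% names(samples),
              "sample table needs a sample_id column")
  samples$sample_id <- as.character(samples$sample_id)
  ns <- nrow(samples)
  if (is.null(samples[["patient_id"]])) samples$patient_id <- samples$sample_id
  if (is.null(samples[["cohort_label"]]))
    samples$cohort_label <- rep("synthetic", ns)
  if (is.null(samples[["panel_id"]])) samples$panel_id <- rep("custom", ns)
  if (is.null(samples[["collection_day"]]))
    samples$collection_day <- rep(NA_integer_, ns)
  assert_that(!anyDuplicated(samples$sample_id),
              "duplicate sample_id in sample table")
  orphans <- setdiff(variants$sample_id, samples$sample_id)
  if (length(orphans))
    stop_mrd("variants reference unknown sample(s): ",
             paste(unique(orphans), collapse = ", "))
  if (!is.null(covered_genes)) {
    assert_that(is.list(covered_genes) && !is.null(names(covered_genes)),
                "covered_genes must be a named list of gene vectors")
    covered_genes <- lapply(covered_genes, normalize_gene)
    panel_of <- samples$panel_id[match(variants$sample_id, samples$sample_id)]
    for (p in unique(panel_of)) {
      cov <- covered_genes[[p]]
      if (is.null(cov)) next
      out <- setdiff(variants$gene[panel_of == p], cov)
      if (length(out))
        stop_mrd("gene(s) not covered by panel '", p, "': ",
                 paste(out, collapse = ", "))
    }
  }
  structure(list(variants = variants, samples = samples,
                 covered_genes = covered_genes),
            class = "ctdna_cohort")
}

# per-row invariant check; returns "" for valid rows, message otherwise
validate_variant_rows <- function(v) {
  msg <- character(nrow(v))
  bad_vaf <- is.na(v$vaf) | v$vaf < 0 | v$vaf > 1
  msg[bad_vaf] <- "vaf outside [0,1] or unparsable"
  blank_gene <- !nzchar(v$gene) | is.na(v$gene)
  msg[blank_gene] <- "empty gene symbol"
  blank_cdot <- !nzchar(v$cdot) | is.na(v$cdot)
  msg[blank_cdot] <- "empty cdot"
  bad_type <- !(v$variant_type %in% VARIANT_TYPES)
  msg[bad_type & !nzchar(msg)] <- "unknown variant_type"
  promoter_pdot <- v$variant_class == "promoter" & nzchar(v$pdot)
  msg[promoter_pdot & !nzchar(msg)] <- "promoter variant carries a pdot"
  msg
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat("ctDNA cohort variant table\n")
  cat("  samples : ", nrow(x$samples), "\n", sep = "")
  cat("  variants: ", nrow(x$variants), " in ",
      length(unique(x$variants$gene)), " genes\n", sep = "")
  if (!is.null(x$covered_genes))
    cat("  panels  : ",
        paste(sprintf("%s (%d genes)", names(x$covered_genes),
                      vapply(x$covered_genes, length, 1L)), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Read a MAF-like tab-separated variant table
#'
#' Expected header (tab-separated, UTF-8): `sample_id`, `gene`,
#' `chromosome`, `exon`, `cdot`, `pdot`, `vaf`, `variant_type`; only
#' `sample_id`, `gene`, `cdot`, `vaf` and `variant_type` are mandatory.
#' Rows violating row invariants (VAF outside \[0,1\], empty gene/cdot,
#' unknown type) are rejected individually: they are dropped from the
#' returned table, reported via a warning, and listed row-indexed in the
#' `row_errors` attribute — never silently.
#'
#' @param path file path.
#' @param dialect input dialect; only `"maf_like_tsv"` is defined.
#' @param samples,covered_genes forwarded to [cohort_variant_table()].
#' @return a `ctdna_cohort`; attribute `row_errors` holds a data.frame
#'   (`row`, `message`) for rejected rows.
#' @export
read_variant_table <- function(path, dialect = "maf_like_tsv",
                               samples = NULL, covered_genes = NULL) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), paste0("no such file: ", path))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", check.names = FALSE)
  cmap <- c(sample_id = "sample_id", gene = "gene", chromosome = "chrom",
            exon = "exon_label", cdot = "cdot", pdot = "pdot",
            vaf = "vaf", variant_type = "variant_type")
  mandatory <- c("sample_id", "gene", "cdot", "vaf", "variant_type")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop_mrd("variant table format error; missing column(s): ",
             paste(miss, collapse = ", "))
  v <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                  matrix(nrow = nrow(raw), ncol = 0))
  for (src in names(cmap))
    v[[cmap[[src]]]] <- if (src %in% names(raw)) raw[[src]] else ""
  suppressWarnings(v$vaf <- as.numeric(v$vaf))
  v$gene <- normalize_gene(v$gene)
  v$pdot[is.na(v$pdot)] <- ""
  v$variant_class <- classify_variant(v$cdot, v$pdot)
  msg <- validate_variant_rows(v)
  bad <- nzchar(msg)
  row_errors <- data.frame(row = which(bad), message = msg[bad],
                           stringsAsFactors = FALSE)
  if (nrow(row_errors))
    warning(sprintf("%d of %d rows rejected (see attr(., 'row_errors'))",
                    nrow(row_errors), nrow(raw)), call. = FALSE)
  tab <- cohort_variant_table(v[!bad, , drop = FALSE], samples = samples,
                              covered_genes = covered_genes)
  attr(tab, "row_errors") <- row_errors
  tab
}

#' Write a cohort variant table as MAF-like TSV
#'
#' Inverse of [read_variant_table()]: a write/read round trip reproduces
#' all variant fields.
#'
#' @param cohort a `ctdna_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(cohort, path) {
  v <- cohort$variants
  out <- data.frame(sample_id = v$sample_id, gene = v$gene,
                    chromosome = v$chrom, exon = v$exon_label,
                    cdot = v$cdot, pdot = v$pdot,
                    vaf = format(v$vaf, digits = 17, scientific = FALSE,
                                 trim = TRUE),
                    variant_type = v$variant_type,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a minimal single-sample VCF as a cohort variant table
#'
#' Supports VCF v4.x with one sample column. One call is emitted per ALT
#' allele; the variant type is inferred from REF/ALT lengths (equal →
#' substitution, REF longer → deletion, ALT longer → insertion). The
#' variant allele fraction is looked up in the named FORMAT field first,
#' then in INFO; per-allele comma-separated values are honored. Gene and
#' HGVS annotations are taken from INFO keys `GENE`, `CDOT` and `PDOT`
#' when present; absent a `CDOT`, a genomic-style `g.` description is
#' synthesized so that every call carries a non-empty coding label.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @param vaf_field name of the FORMAT or INFO field holding the VAF
#'   (default `"AF"`).
#' @param sample_id sample identifier; defaults to the VCF sample column
#'   name.
#' @return a `ctdna_cohort` with one sample.
#' @export
read_minimal_vcf <- function(path, vaf_field = "AF", sample_id = NULL) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  has_gt <- !is.null(vcf@gt) && ncol(vcf@gt) >= 2
  if (has_gt && ncol(vcf@gt) > 2)
    stop_mrd("multi-sample VCF is unsupported; found ",
             ncol(vcf@gt) - 1, " sample columns")
  if (is.null(sample_id))
    sample_id <- if (has_gt) colnames(vcf@gt)[2] else "sample1"

  vaf_raw <- NULL
  if (has_gt) {
    gt <- tryCatch(vcfR::extract.gt(vcf, element = vaf_field,
                                    as.numeric = FALSE),
                   error = function(e) NULL)
    if (!is.null(gt) && !all(is.na(gt))) vaf_raw <- gt[, 1]
  }
  if (is.null(vaf_raw)) {
    info <- vcfR::extract.info(vcf, element = vaf_field)
    if (is.null(info) || all(is.na(info)))
      stop_mrd("VAF field '", vaf_field,
               "' not found in FORMAT or INFO")
    vaf_raw <- info
  }
  gene <- vcfR::extract.info(vcf, element = "GENE")
  cdot <- vcfR::extract.info(vcf, element = "CDOT")
  pdot <- vcfR::extract.info(vcf, element = "PDOT")

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    vafs <- strsplit(as.character(vaf_raw[i]), ",", fixed = TRUE)[[1]]
    if (length(vafs) == 1) vafs <- rep(vafs, length(alts))
    assert_that(length(vafs) == length(alts),
                sprintf("record %d: %d ALT alleles but %d VAF values",
                        i, length(alts), length(vafs)))
    ref <- fix[i, "REF"]
    for (j in seq_along(alts)) {
      alt <- alts[[j]]
      type <- if (nchar(ref) == nchar(alt)) "Substitution"
              else if (nchar(ref) > nchar(alt)) "Deletion" else "Insertion"
      cd <- if (!is.null(cdot) && !is.na(cdot[i])) cdot[i] else
        sprintf("g.%s%s>%s", fix[i, "POS"], ref, alt)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id,
        gene = if (!is.null(gene) && !is.na(gene[i])) gene[i] else
          paste0(fix[i, "CHROM"], ":", fix[i, "POS"]),
        chrom = fix[i, "CHROM"], exon_label = "",
        cdot = cd,
        pdot = if (!is.null(pdot) && !is.na(pdot[i])) pdot[i] else "",
        vaf = as.numeric(vafs[[j]]), variant_type = type,
        stringsAsFactors = FALSE)
    }
  }
  v <- do.call(rbind, rows)
  cohort_variant_table(v)
}
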