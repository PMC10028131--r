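#' Classify a variant from its HGVS coding and protein descriptions
#'
#' Deterministic, regex-driven classification that never consults a
#' transcript database. Rules, in order of precedence on the protein
#' change: `fs` → frameshift indel; trailing `*` (nonsense) → stopgain;
#' `del`/`ins`/`dup` without `fs` → non-frameshift indel; `X###Y` with
#' `Y == X` → synonymous, otherwise missense. With an empty or
#' unparsable protein change the coding change decides: a negative
#' (upstream) position → promoter; an intronic offset of one or two
#' bases from an exon boundary (e.g. `c.97-2A>T`) → splice site.
#' Anything else is `other`; the function never throws on malformed
#' input.
#'
#' @param cdot character vector of HGVS coding changes (non-empty).
#' @param pdot character vector of HGVS protein changes (may be empty
#'   strings).
#' @return character vector of class labels among
#'   `r paste(ALL_CLASSES, collapse = ", ")`.
#' @examples
#' classify_variant("c.6596A>T", "p.Q2199L")   # missense
#' classify_variant("c.4427del", "p.N1476Tfs*12") # frameshift_indel
#' classify_variant("c.-124C>T", "")           # promoter
#' classify_variant("c.97-2A>T", "")           # splice_site
#' @export
classify_variant <- function(cdot, pdot) {
  n <- max(length(cdot), length(pdot))
  cdot <- rep_len(as.character(cdot), n)
  pdot <- rep_len(as.character(pdot), n)
  pdot[is.na(pdot)] <- ""
  cdot[is.na(cdot)] <- ""
  p <- sub("^p\\.", "", trimws(pdot))
  cls <- rep("other", n)

  has_p <- nzchar(p)
  fs <- has_p & grepl("fs", p, fixed = TRUE)
  nonsense <- has_p & !fs & grepl("\\*$", p)
  indel <- has_p & !fs & !nonsense &
    grepl("(del|ins|dup)", p)
  # simple substitution p.X###Y (three-letter codes not used in this
  # assay's annotation; one-letter only)
  sub_m <- regmatches(p, regexec("^([A-Z])([0-9]+)([A-Z])$", p))
  is_sub <- has_p & vapply(sub_m, length, 1L) == 4L
  syn <- is_sub & vapply(sub_m, function(m)
    length(m) == 4L && m[2] == m[4], logical(1))

  cls[is_sub & !syn] <- "missense"
  cls[syn] <- "synonymous"
  cls[indel] <- "nonframeshift_indel"
  cls[nonsense] <- "stopgain"
  cls[fs] <- "frameshift_indel"

  cd <- trimws(cdot)
  no_p <- !has_p
  promoter <- no_p & grepl("^c\\.-[0-9]+", cd)
  splice <- no_p & grepl("^c\\.[0-9]+([-+])[12]([ACGT]|_|del|ins|dup)", cd)
  cls[splice] <- "splice_site"
  cls[promoter] <- "promoter"
  cls
}

#' Retain the variant classes used for all downstream analysis
#'
#' Keeps missense, stopgain, frameshift-indel and non-frameshift-indel
#' calls. With `keep_noncoding_hotspots = TRUE` (the default) promoter
#' and splice-site calls are additionally retained, so that recurrent
#' non-coding hotspots such as the TERT promoter stay visible to the MRD
#' rule; the strict four-class rule is available by turning the flag
#' off. The filter is idempotent and never adds variants.
#'
#' @param cohort a `ctdna_cohort`.
#' @param keep_noncoding_hotspots logical; default `TRUE`.
#' @return filtered `ctdna_cohort` (samples and panel coverage
#'   untouched).
#' @export
retention_filter <- function(cohort, keep_noncoding_hotspots = TRUE) {
  keep <- RETAINED_CLASSES
  if (keep_noncoding_hotspots) keep <- c(keep, NONCODING_HOTSPOT_CLASSES)
  cohort$variants <-
    cohort$variants[cohort$variants$variant_class %in% keep, , drop = FALSE]
  rownames(cohort$variants) <- NULL
  cohort
}

#' Parse an HGVS protein change into residue position and change kind
#'
#' Extracts the first residue index and a coarse change kind
#' (substitution, nonsense, frameshift, in-frame deletion/insertion,
#' other). Unparsable input yields `ok = FALSE` rather than an error.
#'
#' @param pdot character vector of protein change strings.
#' @return data.frame with columns `pdot`, `position` (integer, `NA`
#'   when unparsable), `kind`, `ok`.
#' @examples
#' parse_protein_change(c("p.Q2199L", "p.N1476Tfs*12", "p.E404del"))
#' @export
parse_protein_change <- function(pdot) {
  p <- sub("^p\\.", "", trimws(as.character(pdot)))
  p[is.na(p)] <- ""
  m <- regmatches(p, regexpr("[0-9]+", p))
  pos <- rep(NA_integer_, length(p))
  has <- regexpr("[0-9]+", p) > 0
  pos[has] <- as.integer(regmatches(p, regexpr("[0-9]+", p)))
  kind <- rep("other", length(p))
  kind[grepl("fs", p, fixed = TRUE)] <- "frameshift"
  plain <- !grepl("fs", p, fixed = TRUE)
  kind[plain & grepl("\\*$", p)] <- "nonsense"
  kind[plain & grepl("del", p, fixed = TRUE) & !grepl("ins", p, fixed = TRUE)] <- "inframe_del"
  kind[plain & grepl("(ins|dup)", p)] <- "inframe_ins"
  is_sub <- plain & grepl("^[A-Z][0-9]+[A-Z]$", p) & !grepl("\\*$", p)
  kind[is_sub] <- "substitution"
  ok <- has & kind != "other"
  data.frame(pdot = pdot, position = pos, kind = kind, ok = ok,
             stringsAsFactors = FALSE)
}
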