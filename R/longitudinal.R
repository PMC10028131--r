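#' Track MRD status across serial plasma samples of one patient
#'
#' Applies the MRD calling rule independently at every timepoint
#' (status at a timepoint never depends on other timepoints), then
#' derives the trajectory-level summaries: the conversion time (first
#' observed negative-to-positive transition only; later re-conversions
#' are listed in `transitions` but do not redefine it), the time of the
#' first positive call, and — when a clinical relapse time is supplied
#' — the lead time from first MRD positivity to relapse. A negative
#' lead time (first positivity after the recorded relapse) is emitted
#' with `post_relapse = TRUE` rather than suppressed. A flag reports
#' whether the maximal VAF increases strictly across consecutive
#' positive timepoints (rising circulating tumor burden).
#'
#' @param timepoints list where each element is a list/data.frame with
#'   `time_months` (scalar) and `variants` (data.frame of that draw's
#'   variants, possibly empty), and optionally `clinical_markers`
#'   (named numeric, e.g. AFP in ug/L, PIVKA-II in mAU/ml; carried as
#'   annotations, never used in calling) and `imaging_finding` (free
#'   text).
#' @param panel an `mrd_panel` or gene vector.
#' @param relapse_time clinical relapse time in months, or `NULL`.
#' @param patient_id identifier for the trajectory.
#' @return object of class `mrd_trajectory`: `patient_id`, `calls`
#'   (data.frame `time_months`, `status`, `n_monitoring_genes`,
#'   `max_vaf`), `results` (per-timepoint `mrd_call` list),
#'   `clinical_markers` (data.frame or NULL), `conversion_time`,
#'   `first_positive_time`, `relapse_time`, `lead_time_months`,
#'   `post_relapse`, `transitions` (data.frame `time_months`, `from`,
#'   `to`), `max_vaf_increasing`.
#' @examples
#' tp <- list(
#'   list(time_months = 0.25, variants = data.frame(
#'     sample_id = "B", gene = "FAT1", cdot = "c.300C>T", pdot = "p.R100W",
#'     vaf = 0.004, variant_type = "Substitution")),
#'   list(time_months = 6, variants = data.frame(
#'     sample_id = "B", gene = "CREBBP", cdot = "c.6596A>T",
#'     pdot = "p.Q2199L", vaf = 0.0050933, variant_type = "Substitution")))
#' track_mrd(tp, default_hcc_panel(), relapse_time = 11)
#' @export
track_mrd <- function(timepoints, panel, relapse_time = NULL,
                      patient_id = NULL) {
  assert_that(length(timepoints) >= 1, "need at least one timepoint")
  times <- vapply(timepoints, function(tp) as.numeric(tp$time_months), 1)
  assert_that(all(times >= 0), "timepoint times must be >= 0")
  if (anyDuplicated(times))
    stop_mrd("duplicate timepoint times: ",
             paste(unique(times[duplicated(times)]), collapse = ", "))
  if (is.unsorted(times)) {
    warning("timepoints were not sorted by time; sorting", call. = FALSE)
    timepoints <- timepoints[order(times)]
    times <- sort(times)
  }
  results <- lapply(timepoints, function(tp)
    call_mrd(tp$variants, panel, sample_id = patient_id))
  status <- vapply(results, `[[`, "", "status")
  calls <- data.frame(
    time_months = times, status = status,
    n_monitoring_genes = vapply(results, `[[`, 1L, "n_panel_genes_hit"),
    max_vaf = vapply(results, `[[`, 1, "max_vaf"),
    stringsAsFactors = FALSE)
  markers <- lapply(seq_along(timepoints), function(i) {
    cm <- timepoints[[i]]$clinical_markers
    if (is.null(cm)) return(NULL)
    cbind(data.frame(time_months = times[i]), as.data.frame(as.list(cm)))
  })
  markers <- markers[!vapply(markers, is.null, TRUE)]
  markers <- if (length(markers)) do.call(rbind, markers) else NULL

  pos <- status == "positive"
  first_pos <- if (any(pos)) times[which(pos)[1]] else NA_real_
  trans_idx <- which(status[-1] != status[-length(status)])
  transitions <- data.frame(time_months = times[trans_idx + 1L],
                            from = status[trans_idx],
                            to = status[trans_idx + 1L],
                            stringsAsFactors = FALSE)
  conv_idx <- which(transitions$from == "negative" &
                      transitions$to == "positive")
  conversion_time <- if (length(conv_idx))
    transitions$time_months[conv_idx[1]] else NA_real_
  lead <- if (!is.null(relapse_time) && !is.na(first_pos))
    relapse_time - first_pos else NA_real_
  pos_vafs <- calls$max_vaf[pos]
  structure(list(
    patient_id = patient_id, calls = calls, results = results,
    clinical_markers = markers,
    conversion_time = conversion_time,
    first_positive_time = first_pos,
    relapse_time = relapse_time %||% NA_real_,
    lead_time_months = lead,
    post_relapse = !is.na(lead) && lead < 0,
    transitions = transitions,
    max_vaf_increasing = length(pos_vafs) >= 2 &&
      all(diff(pos_vafs) > 0)),
    class = "mrd_trajectory")
}

#' @export
print.mrd_trajectory <- function(x, ...) {
  cat("MRD trajectory", if (!is.null(x$patient_id)) x$patient_id else "",
      "over", nrow(x$calls), "timepoints\n")
  print(x$calls, row.names = FALSE)
  if (!is.na(x$conversion_time))
    cat("conversion (neg->pos) at", x$conversion_time, "months\n")
  if (!is.na(x$lead_time_months))
    cat("lead time to relapse:", x$lead_time_months, "months",
        if (x$post_relapse) "(first positivity after relapse)" else "",
        "\n")
  if (isTRUE(x$max_vaf_increasing))
    cat("maximal VAF strictly increasing across positive draws\n")
  invisible(x)
}

#' Read a longitudinal variant table
#'
#' Tab-separated long format: `patient_id`, `time_months`, then the
#' MAF-like variant columns (`gene`, `cdot`, `pdot`, `vaf`,
#' `variant_type`, ...). A row with an empty `gene` records a draw with
#' no variants.
#'
#' @param path file path.
#' @return named list (per patient) of timepoint lists suitable for
#'   [track_mrd()].
#' @export
read_longitudinal_table <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "gene", "cdot", "vaf",
            "variant_type")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_mrd("longitudinal table missing column(s): ",
             paste(miss, collapse = ", "))
  lapply(split(d, d$patient_id), function(dp) {
    lapply(split(dp, dp$time_months), function(tp) {
      v <- tp[nzchar(tp$gene), , drop = FALSE]
      v$sample_id <- v$patient_id
      list(time_months = tp$time_months[1],
           variants = v[, setdiff(names(v),
                                  c("patient_id", "time_months")),
                        drop = FALSE])
    })
  })
}
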