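#' Estimate per-locus background error rates from control observations
#'
#' Pseudocount-smoothed pooled rate per locus:
#' `(sum(alt) + alpha0) / (sum(depth) + beta0)`, with defaults
#' `alpha0 = 1`, `beta0 = 1000`. The smoothing keeps rates strictly
#' positive (a locus never observed in error still gets a floor of
#' about 1/beta0) and strictly below 1.
#'
#' @param control_counts data.frame with columns `locus_id`, `alt`,
#'   `depth`; several control observations per locus are pooled.
#' @param alpha0,beta0 pseudocounts added to alt reads and depth.
#' @return named numeric vector of error rates per locus.
#' @examples
#' estimate_background(data.frame(locus_id = "L1", alt = 0, depth = 10000))
#' @export
estimate_background <- function(control_counts, alpha0 = 1,
                                beta0 = 1000) {
  need <- c("locus_id", "alt", "depth")
  miss <- setdiff(need, names(control_counts))
  if (length(miss))
    stop_mrd("control_counts missing column(s): ",
             paste(miss, collapse = ", "))
  alt <- tapply(control_counts$alt, control_counts$locus_id, sum)
  depth <- tapply(control_counts$depth, control_counts$locus_id, sum)
  assert_that(all(depth > 0), "zero total control depth at some locus")
  rate <- (alt + alpha0) / (depth + beta0)
  assert_that(all(rate < 1), "background rate >= 1; check inputs")
  stats::setNames(as.numeric(rate), names(alt))
}

#' Binomial low-VAF locus calling with FDR control
#'
#' For each locus the alt-read count is tested against its background
#' error rate with a one-sided exact binomial tail,
#' `p = P(X >= alt_count)` for `X ~ Binomial(depth, error_rate)`.
#' P-values are Benjamini-Hochberg adjusted across the batch and a
#' locus is called when `q < alpha` and the alt count meets the
#' supporting-read floor `min_alt` (guarding single-read artifacts).
#'
#' @param counts data.frame with `locus_id`, `depth`, `alt_count` and
#'   either a `background_error_rate` column or the `error_rate`
#'   argument.
#' @param error_rate optional scalar or per-locus error rate vector
#'   overriding the column.
#' @param alpha FDR level; default 0.05.
#' @param min_alt minimum alt reads for a call; default 3.
#' @return data.frame (`locus_id`, `depth`, `alt_count`, `error_rate`,
#'   `vaf`, `p_value`, `q_value`, `called`).
#' @export
call_loci <- function(counts, error_rate = NULL, alpha = 0.05,
                      min_alt = 3) {
  need <- c("locus_id", "depth", "alt_count")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop_mrd("counts missing column(s): ", paste(miss, collapse = ", "))
  e <- error_rate %||% counts[["background_error_rate"]]
  assert_that(!is.null(e), "no background error rate supplied")
  e <- rep_len(e, nrow(counts))
  assert_that(all(counts$alt_count >= 0 &
                    counts$alt_count <= counts$depth),
              "alt_count must lie in [0, depth]")
  p <- binom_tail_p(counts$alt_count, counts$depth, e)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(locus_id = counts$locus_id, depth = counts$depth,
             alt_count = counts$alt_count, error_rate = e,
             vaf = ifelse(counts$depth > 0,
                          counts$alt_count / counts$depth, 0),
             p_value = p, q_value = q,
             called = q < alpha & counts$alt_count >= min_alt,
             stringsAsFactors = FALSE)
}

#' Exact upper binomial tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`; `k = 0` gives 1 exactly.
#'
#' @param k alt-read counts.
#' @param n depths.
#' @param p success (error) rates.
#' @return numeric vector of tail probabilities.
#' @export
binom_tail_p <- function(k, n, p) {
  ifelse(k <= 0, 1, stats::pbinom(k - 1, n, p, lower.tail = FALSE))
}

#' Read / write pileup count tables
#'
#' Tab-separated with header `locus_id`, `depth`, `alt_count` and
#' optional `background_error_rate`, `truth` columns.
#'
#' @param path file path.
#' @return data.frame of pileup counts.
#' @export
read_pileup_table <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_pileup_table
#' @param counts data.frame of pileup counts (or [call_loci()] output).
#' @export
write_pileup_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
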