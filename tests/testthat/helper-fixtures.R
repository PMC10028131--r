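# Shared fixtures and independent oracles used across the suite.

mrdpos_fixture_path <- function() {
  system.file("extdata", "mrd_positive_variants.tsv", package = "hccMRD")
}

mrdpos_fixture_cohort <- function() {
  read_variant_table(mrdpos_fixture_path())
}

# hand-assigned classes for the 13 fixture rows, in file order
fixture_hand_classes <- c(
  "missense", "nonframeshift_indel", "missense", "missense",
  "stopgain", "stopgain", "frameshift_indel", "frameshift_indel",
  "frameshift_indel", "frameshift_indel", "promoter", "missense",
  "splice_site")

# --- independent oracles -------------------------------------------------

# product-limit estimator computed from first principles
oracle_km <- function(time, event) {
  o <- order(time)
  time <- time[o]; event <- event[o]
  tt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = tt, surv = surv)
}

# 1-df log-rank statistic from observed-vs-expected sums over pooled
# event times (hypergeometric variance)
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in tt) {
    n <- sum(time >= t); n1 <- sum(time >= t & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# two-sided Fisher exact p by hypergeometric enumeration: total mass of
# tables (at fixed margins) no more probable than the observed one,
# with a relative tie tolerance for floating point comparisons
oracle_fisher_p <- function(n11, n10, n01, n00, tol = 1e-7) {
  m <- n11 + n10; n <- n01 + n00; k <- n11 + n01
  lo <- max(0, k - n); hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(n11, m, n, k)
  sum(dens[dens <= obs * (1 + tol)])
}

# Benjamini-Hochberg step-up from first principles
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# exact binomial upper tail by direct summation of the mass function
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}

# chi-square statistic from Sum (O - E)^2 / E
oracle_chisq_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
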