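#' Confusion metrics of MRD status against early relapse
#'
#' Early relapse is a relapse event within `early_relapse_window` months
#' of surgery (default 24, the conventional early-relapse horizon in
#' resected HCC). `tp` counts MRD-positive early relapsers, `fp`
#' MRD-positive non-relapsers, and so on. Ratios with zero denominators
#' are returned as `NA` with the affected metric named in `undefined`,
#' never as silent `NaN`s. Positive predictive value is reported
#' alongside specificity because the two are easy to conflate when both
#' equal 100%: specificity is `tn/(tn+fp)` over non-relapsers, PPV is
#' `tp/(tp+fp)` over positive calls.
#'
#' @param mrd_status named character/logical vector per patient
#'   (`"positive"`/`"negative"` or `TRUE`/`FALSE`).
#' @param early_relapse named logical vector per patient, or a
#'   data.frame of survival records (columns `patient_id`,
#'   `time_months`, `event`) from which the flag is derived as
#'   `event == 1 & time_months <= early_relapse_window`.
#' @param early_relapse_window months; default 24.
#' @return object of class `confusion_metrics`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `undefined` (character
#'   vector of undefined metrics).
#' @export
confusion_metrics <- function(mrd_status, early_relapse,
                              early_relapse_window = 24) {
  pos <- to_logical_status(mrd_status)
  if (is.data.frame(early_relapse)) {
    rel <- stats::setNames(
      early_relapse$event == 1 &
        early_relapse$time_months <= early_relapse_window,
      early_relapse$patient_id)
  } else rel <- early_relapse
  if (!is.null(names(pos)) && !is.null(names(rel))) {
    if (!setequal(names(pos), names(rel)))
      stop_mrd("mrd_status and early_relapse cover different patients")
    rel <- rel[names(pos)]
  } else assert_that(length(pos) == length(rel),
                     "mrd_status and early_relapse lengths differ")
  tp <- sum(pos & rel); fp <- sum(pos & !rel)
  tn <- sum(!pos & !rel); fn <- sum(!pos & rel)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              sensitivity = safe(tp, tp + fn),
              specificity = safe(tn, tn + fp),
              ppv = safe(tp, tp + fp),
              npv = safe(tn, tn + fn))
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv")], is.na, TRUE)))
  structure(out, class = "confusion_metrics")
}

to_logical_status <- function(x) {
  if (is.logical(x)) return(x)
  lv <- tolower(as.character(x))
  assert_that(all(lv %in% c("positive", "negative")),
              "mrd_status must be positive/negative or logical")
  stats::setNames(lv == "positive", names(x))
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("sensitivity %s  specificity %s  ppv %s  npv %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv),
              fmt(x$npv)))
  invisible(x)
}

#' Kaplan-Meier product-limit estimator
#'
#' Thin wrapper around the standard product-limit fit returning the
#' curve on the event-time grid plus the median survival, defined as
#' the earliest time with S(t) <= 0.5 (`NA` = not reached).
#'
#' @param records data.frame with `time_months` and `event` columns, or
#'   the two vectors passed as `time` / `event`.
#' @param time,event alternative vector interface.
#' @return object of class `km_curve`: `time`, `surv`, `n_risk`,
#'   `n_event`, `median` (months or `NA`), `n`.
#' @export
km_estimator <- function(records = NULL, time = NULL, event = NULL) {
  if (!is.null(records)) {
    time <- records$time_months; event <- records$event
  }
  assert_that(length(time) >= 1, "need at least one record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, censored = TRUE)
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5])
         else NA_real_
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med, n = length(time)),
            class = "km_curve")
}

#' Survival probability of a Kaplan-Meier curve at given times
#'
#' Piecewise-constant (right-continuous) evaluation, with S(t) = 1
#' before the first event/censoring time.
#'
#' @param curve a `km_curve`.
#' @param t numeric times.
#' @return numeric survival probabilities.
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, 1)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve on", x$n, "records;",
      sum(x$n_event), "events; median",
      if (is.na(x$median)) "not reached" else
        paste0(format(x$median), " months"), "\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Months since surgery",
                          ylab = "Relapse-free survival", ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$surv, each = 2)[seq_len(2 * length(x$surv) - 1)])
  plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' One-degree-of-freedom log-rank statistic from the observed-vs-
#' expected event counts over the pooled event times.
#'
#' @param groupA,groupB data.frames with `time_months` and `event`, or
#'   supply `time`, `event`, `group` vectors.
#' @param time,event,group alternative vector interface (`group` with
#'   two levels).
#' @return list `chi_square`, `p_value`, `df`, `n_events`, `defined`
#'   (FALSE with `NA` statistic when there are no events).
#' @export
logrank_test <- function(groupA = NULL, groupB = NULL,
                         time = NULL, event = NULL, group = NULL) {
  if (!is.null(groupA)) {
    time <- c(groupA$time_months, groupB$time_months)
    event <- c(groupA$event, groupB$event)
    group <- rep(c("A", "B"), c(nrow(groupA), nrow(groupB)))
  }
  assert_that(length(unique(group)) == 2, "need exactly two groups")
  assert_that(min(table(group)) >= 1, "each group needs >= 1 patient")
  if (sum(event) == 0)
    return(list(chi_square = NA_real_, p_value = NA_real_, df = 1L,
                n_events = 0L, defined = FALSE))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  list(chi_square = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       df = 1L, n_events = sum(event), defined = TRUE)
}

#' Univariable Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling (Newton-Raphson to
#' gradient tolerance 1e-9, at most 50 iterations), Wald standard
#' error, 95% CI and p-value. With a binary covariate and zero events
#' in one arm the partial likelihood is monotone and the estimate
#' diverges; this is detected and flagged via `converged = FALSE`
#' rather than reported as a finite hazard ratio.
#'
#' @param records data.frame with `time_months`, `event` and the
#'   covariate column.
#' @param covariate name of the covariate column (binary or two-level
#'   categorical; the second sorted level is the exposed arm).
#' @return object of class `cox_result`: `log_hazard_ratio`,
#'   `hazard_ratio`, `wald_se`, `ci95` (low, high), `p_value`,
#'   `converged`, `n`, `n_events`, `term`.
#' @export
cox_univariable <- function(records, covariate = "mrd_status") {
  assert_that(covariate %in% names(records),
              paste0("no covariate column '", covariate, "'"))
  x <- records[[covariate]]
  if (!is.numeric(x)) x <- factor(x)
  assert_that(length(unique(records[[covariate]])) >= 2,
              "constant covariate")
  df <- data.frame(time = records$time_months, event = records$event,
                   x = x)
  # divergence is diagnosed below from the data and the estimate itself
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ x, data = df,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)))
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  monotone <- FALSE
  if (is.factor(x) || length(unique(x)) == 2) {
    ev <- tapply(df$event, df$x, sum)
    monotone <- any(ev == 0)
  }
  converged <- !monotone && is.finite(beta) && is.finite(se) &&
    abs(beta) < 15
  structure(list(log_hazard_ratio = beta, hazard_ratio = exp(beta),
                 wald_se = se,
                 ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = 2 * stats::pnorm(-abs(beta / se)),
                 converged = converged, n = nrow(df),
                 n_events = sum(df$event),
                 term = if (is.factor(x)) levels(x)[2] else covariate),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("HR %.2f (95%% CI %.2f-%.2f), P=%.3g  [%s]\n",
              x$hazard_ratio, x$ci95[1], x$ci95[2], x$p_value,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Baseline characteristics table with per-covariate chi-square tests
#'
#' Contingency counts and column percentages of each categorical
#' covariate against the grouping variable, with a chi-square test of
#' proportions per covariate. Following the common default for such
#' baseline tables the chi-square is computed without continuity
#' correction; `method = "fisher"` switches to the exact test.
#'
#' @param patients data.frame of per-patient records.
#' @param covariates character vector of categorical covariate columns.
#' @param group name of the grouping column (default `"mrd_status"`).
#' @param method `"chisq"` (no Yates correction) or `"fisher"`.
#' @return list with `table` (data.frame: `covariate`, `level`, one
#'   `<group>_n`/`<group>_pct` pair per group level, `total_n`,
#'   `total_pct`) and `tests` (data.frame `covariate`, `statistic`,
#'   `p_value`).
#' @export
baseline_table <- function(patients, covariates, group = "mrd_status",
                           method = c("chisq", "fisher")) {
  method <- match.arg(method)
  g <- factor(patients[[group]])
  assert_that(all(table(g) > 0) && nlevels(g) >= 2,
              "each group must be non-empty")
  rows <- list(); tests <- list()
  for (cv in covariates) {
    f <- factor(patients[[cv]])
    tab <- table(f, g)
    tot <- rowSums(tab)
    block <- data.frame(covariate = cv, level = rownames(tab),
                        stringsAsFactors = FALSE)
    for (lev in levels(g)) {
      block[[paste0(lev, "_n")]] <- as.integer(tab[, lev])
      block[[paste0(lev, "_pct")]] <- 100 * tab[, lev] / sum(tab[, lev])
    }
    block$total_n <- as.integer(tot)
    block$total_pct <- 100 * tot / sum(tab)
    rows[[cv]] <- block
    if (method == "chisq") {
      ts <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      tests[[cv]] <- data.frame(covariate = cv,
                                statistic = unname(ts$statistic),
                                p_value = ts$p.value)
    } else {
      ts <- stats::fisher.test(tab)
      tests[[cv]] <- data.frame(covariate = cv, statistic = NA_real_,
                                p_value = ts$p.value)
    }
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       tests = do.call(rbind, c(tests, make.row.names = FALSE)))
}

#' Read a survival records CSV
#'
#' Columns: `patient_id`, `time_months`, `event` (0/1), `mrd_status`,
#' then arbitrary covariate columns.
#'
#' @param path CSV file path.
#' @return data.frame of survival records.
#' @export
read_survival_table <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  need <- c("patient_id", "time_months", "event")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_mrd("survival table missing column(s): ",
             paste(miss, collapse = ", "))
  assert_that(all(d$time_months >= 0), "negative follow-up time")
  assert_that(all(d$event %in% c(0, 1)), "event flag must be 0/1")
  d
}
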