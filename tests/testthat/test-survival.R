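test_that("confusion metrics reproduce the published surgical-cohort counts", {
  # 6 MRD-positive patients, all with early relapse; 2 of 14 negatives
  # relapsed early
  status <- stats::setNames(rep(c("positive", "negative"), c(6, 14)),
                            sprintf("P%02d", 1:20))
  relapse <- stats::setNames(rep(c(TRUE, FALSE), c(8, 12)),
                             sprintf("P%02d", c(1:6, 7:8, 9:20)))
  cm <- confusion_metrics(status, relapse)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(6, 2, 0, 12))
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 1.0)
  expect_equal(cm$ppv, 1.0)        # the 6/6 count
  expect_equal(cm$npv, 12 / 14)
  expect_length(cm$undefined, 0)
})

test_that("undefined ratios are flagged, not NaN-propagated", {
  status <- stats::setNames(rep("negative", 5), letters[1:5])
  relapse <- stats::setNames(rep(FALSE, 5), letters[1:5])
  cm <- confusion_metrics(status, relapse)
  expect_true(is.na(cm$sensitivity))
  expect_equal(cm$specificity, 1)
  expect_setequal(cm$undefined, c("sensitivity", "ppv"))
  expect_error(confusion_metrics(status,
                                 stats::setNames(rep(FALSE, 5),
                                                 letters[2:6])),
               "different patients")
})

test_that("early-relapse flag derives from survival records at the window", {
  surv <- data.frame(patient_id = c("a", "b", "c"),
                     time_months = c(10, 30, 10),
                     event = c(1, 1, 0))
  status <- stats::setNames(c("positive", "positive", "negative"),
                            c("a", "b", "c"))
  cm <- confusion_metrics(status, surv)
  # b relapsed late (30 > 24) so counts as a false positive
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(1, 1, 1, 0))
})

test_that("Kaplan-Meier estimates match hand product-limit computations", {
  km <- km_estimator(time = 1:4, event = rep(1, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)

  km2 <- km_estimator(time = c(5, 10), event = c(1, 0))
  expect_equal(km_surv_at(km2, 5), 0.5)
  expect_equal(km_surv_at(km2, 4.9), 1)

  all_cens <- km_estimator(time = c(3, 7, 9), event = c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))
  expect_true(is.na(all_cens$median))
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(42)
  tt <- rexp(40, 0.1)
  km <- km_estimator(time = tt, event = rep(1, 40))
  grid <- seq(0, max(tt), length.out = 25)
  emp <- vapply(grid, function(x) mean(tt > x), 1)
  expect_equal(km_surv_at(km, grid), emp, tolerance = 1e-12)
  ork <- oracle_km(tt, rep(1, 40))
  expect_equal(km$surv, ork$surv, tolerance = 1e-12)
})

test_that("log-rank statistic matches the observed-vs-expected oracle", {
  expect_equal(logrank_test(data.frame(time_months = c(1, 2, 3),
                                       event = c(1, 1, 1)),
                            data.frame(time_months = c(1, 2, 3),
                                       event = c(1, 1, 1)))$chi_square,
               0, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    time <- round(rexp(n, 0.1), 2)
    event <- rbinom(n, 1, 0.8)
    group <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    lr <- logrank_test(time = time, event = event, group = group)
    expect_equal(lr$chi_square, oracle_logrank(time, event, group),
                 tolerance = 1e-6)
  }
  nolr <- logrank_test(time = c(1, 2), event = c(0, 0),
                       group = c("A", "B"))
  expect_false(nolr$defined)
})

test_that("strongly separated groups give vanishing log-rank p", {
  sc <- generate_surgical_cohort(
    surgical_sim_config(n_patients = 2000, mrd_prevalence = 0.5,
                        hazard_ratio = 13, baseline_hazard = 0.01,
                        seed = 99))
  lr <- logrank_test(time = sc$survival$time_months,
                     event = sc$survival$event,
                     group = sc$survival$mrd_status)
  expect_lt(lr$p_value, 1e-10)
})

test_that("Cox recovers a simulated hazard ratio within Wald error", {
  sc <- generate_surgical_cohort(
    surgical_sim_config(n_patients = 2000, mrd_prevalence = 0.5,
                        hazard_ratio = 13, baseline_hazard = 0.01,
                        seed = 4))
  cx <- cox_univariable(sc$survival, "mrd_status")
  expect_true(cx$converged)
  expect_lt(abs(cx$log_hazard_ratio - log(13)), 3 * cx$wald_se)
  expect_equal(cx$hazard_ratio, exp(cx$log_hazard_ratio))
  expect_equal(cx$ci95,
               exp(cx$log_hazard_ratio +
                     c(-1, 1) * qnorm(0.975) * cx$wald_se))
})

test_that("swapping group labels negates the log hazard ratio exactly", {
  sc <- generate_surgical_cohort(
    surgical_sim_config(n_patients = 300, mrd_prevalence = 0.4,
                        hazard_ratio = 3, baseline_hazard = 0.02,
                        seed = 8))
  s <- sc$survival
  cx <- cox_univariable(s, "mrd_status")
  s$flipped <- ifelse(s$mrd_status == "positive", "a_pos", "b_neg")
  cx2 <- cox_univariable(s, "flipped")
  expect_equal(cx2$log_hazard_ratio, -cx$log_hazard_ratio,
               tolerance = 1e-8)
})

test_that("monotone likelihood (zero-event arm) is flagged", {
  s <- data.frame(time_months = c(1, 2, 3, 24, 24, 24),
                  event = c(1, 1, 1, 0, 0, 0),
                  mrd_status = rep(c("positive", "negative"), each = 3))
  cx <- suppressWarnings(cox_univariable(s, "mrd_status"))
  expect_false(cx$converged)
  expect_error(cox_univariable(
    data.frame(time_months = 1:3, event = c(1, 0, 1),
               mrd_status = "positive"), "mrd_status"),
    "constant")
})

test_that("baseline table reproduces printed counts and chi-square oracle", {
  pats <- data.frame(
    mrd_status = rep(c("negative", "positive"), c(14, 6)),
    hbv = c(rep("Positive", 11), rep("Negative", 3),
            rep("Positive", 3), rep("Negative", 3)))
  bt <- baseline_table(pats, "hbv", group = "mrd_status")
  row <- bt$table[bt$table$level == "Positive", ]
  expect_equal(row$negative_n, 11L)
  expect_equal(row$positive_n, 3L)
  expect_equal(row$total_n, 14L)
  expect_equal(row$total_pct, 70)
  expect_equal(row$negative_pct, 100 * 11 / 14, tolerance = 1e-12)
  tab <- table(pats$hbv, pats$mrd_status)
  expect_equal(bt$tests$statistic, oracle_chisq_stat(tab),
               tolerance = 1e-10)
  # perfectly balanced 2x2 -> p = 1
  bal <- data.frame(mrd_status = rep(c("n", "p"), each = 10),
                    sex = rep(c("F", "M", "F", "M"), each = 5))
  expect_equal(baseline_table(bal, "sex")$tests$p_value, 1)
  expect_error(baseline_table(pats[pats$mrd_status == "negative", ],
                              "hbv"), "non-empty")
})

test_that("survival CSV reader validates its schema", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(patient_id = "a", time_months = 5, event = 1,
                       mrd_status = "positive"), tmp, row.names = FALSE)
  expect_equal(nrow(read_survival_table(tmp)), 1)
  write.csv(data.frame(patient_id = "a", time_months = -2, event = 1),
            tmp, row.names = FALSE)
  expect_error(read_survival_table(tmp), "negative")
})
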