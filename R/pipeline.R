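#' Assemble a pipeline run configuration
#'
#' Validates all referenced input paths up front, before any stage
#' runs.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in the manifest and driving every
#'   stochastic stage.
#' @param variant_table optional MAF-like TSV of cohort variants; when
#'   `NULL` the simulate stage generates one with the default
#'   calibrated configuration.
#' @param survival_table optional survival CSV; when `NULL` the
#'   simulate stage generates a surgical cohort.
#' @param panel `"default13"` or a path to a panel gene-list file.
#' @param case_threshold,control_threshold panel-screen thresholds.
#' @param alpha significance level for interaction labelling.
#' @param early_relapse_window months; default 24.
#' @param n_samples synthetic cohort size when simulating; default 493.
#' @return object of class `mrd_run_config`.
#' @export
mrd_run_config <- function(out_dir, seed = 1L, variant_table = NULL,
                           survival_table = NULL, panel = "default13",
                           case_threshold = 0.05,
                           control_threshold = 0.10, alpha = 0.05,
                           early_relapse_window = 24,
                           n_samples = 493) {
  for (p in c(variant_table, survival_table,
              if (!identical(panel, "default13")) panel))
    assert_that(file.exists(p), paste0("input path does not exist: ", p))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 variant_table = variant_table,
                 survival_table = survival_table, panel = panel,
                 case_threshold = case_threshold,
                 control_threshold = control_threshold, alpha = alpha,
                 early_relapse_window = early_relapse_window,
                 n_samples = n_samples),
            class = "mrd_run_config")
}

#' Run the MRD analysis pipeline end to end
#'
#' Executes the requested stages in dependency order — simulate (or
#' load), landscape, panel, call, evaluate — writing per-stage TSV/JSON
#' outputs and a JSON run manifest (seed, configuration, per-file MD5
#' checksums). Outputs are pure functions of (inputs, configuration,
#' seed): re-running with the same configuration reproduces identical
#' files. A stage failure halts the run with the failing stage named.
#'
#' @param config an `mrd_run_config`.
#' @param stages character subset of
#'   `c("simulate", "landscape", "panel", "call", "evaluate")`.
#' @return the manifest (invisibly), also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_mrd_pipeline <- function(config,
                             stages = c("simulate", "landscape",
                                        "panel", "call", "evaluate")) {
  assert_that(inherits(config, "mrd_run_config"),
              "config must come from mrd_run_config()")
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(name) {
    outputs <<- c(outputs, file.path(config$out_dir, name))
    file.path(config$out_dir, name)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_mrd("stage '", name, "' failed: ", conditionMessage(e)))
  }
  cohort <- surv <- NULL

  if ("simulate" %in% stages || is.null(config$variant_table)) {
    run_stage("simulate", {
      sim_cfg <- cohort_sim_config(n_samples = config$n_samples,
                                   seed = derive_seed(config$seed, 1))
      cohort <- generate_cohort(sim_cfg)
      write_variant_table(cohort, emit("cohort_variants.tsv"))
      if (is.null(config$survival_table)) {
        sc <- generate_surgical_cohort(
          surgical_sim_config(seed = derive_seed(config$seed, 2),
                              early_relapse_window =
                                config$early_relapse_window))
        surv <- sc$survival
        write_variant_table(sc$cohort, emit("surgical_variants.tsv"))
        utils::write.csv(surv, emit("surgical_survival.csv"),
                         row.names = FALSE)
      }
    })
  }
  if (!is.null(config$variant_table))
    run_stage("load", {
      cohort <- read_variant_table(config$variant_table)
    })
  if (!is.null(config$survival_table))
    run_stage("load", {
      surv <- read_survival_table(config$survival_table)
    })
  cohort <- retention_filter(cohort)

  freqs <- NULL
  if ("landscape" %in% stages) run_stage("landscape", {
    freqs <- gene_mutation_frequency(cohort)
    utils::write.table(freqs, emit("gene_frequencies.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary <- list(
      n_samples = nrow(cohort$samples),
      detection_rate = detection_rate(cohort),
      variant_classes = as.list(variant_class_summary(cohort)),
      snv_classes = as.list(snv_class_summary(cohort)),
      variants_per_sample = variants_per_sample(cohort)[
        c("median", "min", "max")])
    jsonlite::write_json(summary, emit("landscape_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  panel <- NULL
  if ("panel" %in% stages || "call" %in% stages) run_stage("panel", {
    panel <- if (identical(config$panel, "default13"))
      default_hcc_panel()
    else structure(list(genes = read_panel_genes(config$panel),
                        case_threshold = config$case_threshold,
                        control_threshold = config$control_threshold,
                        provenance = c(case = config$panel,
                                       control = ""),
                        audit = NULL, empty = FALSE),
                   class = "mrd_panel")
    write_panel_genes(panel, emit("panel_genes.txt"))
  })

  mrd <- NULL
  if ("call" %in% stages) run_stage("call", {
    target <- if (!is.null(surv)) {
      # call on the cohort the survival records describe when available
      if (exists("sc", inherits = FALSE)) sc$cohort else cohort
    } else cohort
    mrd <- cohort_mrd(target, panel)
    utils::write.table(mrd$calls, emit("mrd_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  if ("evaluate" %in% stages) run_stage("evaluate", {
    assert_that(!is.null(surv),
                "evaluate stage needs survival records (simulate or supply survival_table)")
    status <- stats::setNames(surv$mrd_status, surv$patient_id)
    cm <- confusion_metrics(status, surv,
                            early_relapse_window =
                              config$early_relapse_window)
    lr <- logrank_test(time = surv$time_months, event = surv$event,
                       group = surv$mrd_status)
    cox <- tryCatch(cox_univariable(surv, "mrd_status"),
                    error = function(e) NULL)
    res <- list(
      confusion = unclass(cm),
      logrank = lr,
      cox = if (!is.null(cox)) unclass(cox) else "not estimable",
      km_median_positive = km_estimator(
        surv[surv$mrd_status == "positive", , drop = FALSE])$median,
      km_median_negative = km_estimator(
        surv[surv$mrd_status == "negative", , drop = FALSE])$median)
    jsonlite::write_json(res, emit("evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("hccMRD")),
    seed = config$seed,
    config = unclass(config),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}
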