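PIPELINE_KEYS <- c("seed", "output_dir", "endpoint", "cutoffs",
                   "simulation", "inputs", "log_level")
CUTOFF_KEYS <- c("score", "ctc", "ca153")

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or an equivalent named list and returns the
#' fully resolved configuration with defaults filled in, or fails with a
#' message aggregating every violation found (not just the first).
#' Either a \code{simulation} block (passed to [simulationConfig()]) or
#' an \code{inputs} block (paths \code{control_counts},
#' \code{patient_counts}, \code{clinical}, optional
#' \code{arm_definitions}) must be present.
#'
#' @param config YAML path or named list with keys \code{seed},
#'   \code{output_dir}, optional \code{endpoint} (\code{"pfs"}, the
#'   default, or \code{"os"}), optional \code{cutoffs} (\code{score},
#'   \code{ctc} default 5; \code{ca153} default 30), and one of
#'   \code{simulation} / \code{inputs}.
#' @return resolved configuration list of class \code{runConfig}.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  if (is.null(config$seed) || !is.numeric(config$seed))
    problems <- c(problems, "'seed' (integer) is required")
  if (is.null(config$output_dir))
    problems <- c(problems, "'output_dir' is required")
  config$endpoint <- config$endpoint %||% "pfs"
  if (!config$endpoint %in% c("pfs", "os"))
    problems <- c(problems, "'endpoint' must be 'pfs' or 'os'")
  cut <- config$cutoffs %||% list()
  bad_cut <- setdiff(names(cut), CUTOFF_KEYS)
  if (length(bad_cut))
    problems <- c(problems, sprintf("unknown cutoff key(s): %s",
                                    paste(bad_cut, collapse = ", ")))
  config$cutoffs <- list(score = cut$score %||% 5, ctc = cut$ctc %||% 5,
                         ca153 = cut$ca153 %||% 30)
  nonpos <- vapply(config$cutoffs, function(v)
    !is.numeric(v) || v <= 0, logical(1))
  if (any(nonpos))
    problems <- c(problems, sprintf("cutoff(s) must be positive: %s",
                                    paste(names(nonpos)[nonpos],
                                          collapse = ", ")))
  has_sim <- !is.null(config$simulation)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    problems <- c(problems,
                  "exactly one of 'simulation' or 'inputs' is required")
  if (has_inp) {
    need <- c("control_counts", "patient_counts", "clinical")
    for (k in need)
      if (is.null(config$inputs[[k]]))
        problems <- c(problems, sprintf("inputs.%s is required", k))
      else if (!file.exists(config$inputs[[k]]))
        problems <- c(problems, sprintf("inputs.%s does not exist: %s", k,
                                        config$inputs[[k]]))
    ad <- config$inputs$arm_definitions
    if (!is.null(ad) && !file.exists(ad))
      problems <- c(problems,
                    sprintf("inputs.arm_definitions does not exist: %s", ad))
  }
  if (length(problems))
    stopf("invalid configuration:\n  - %s",
          paste(problems, collapse = "\n  - "))
  class(config) <- "runConfig"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tidyTests <- function(tests) {
  do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(analysis = nm, method = t$method, statistic = t$statistic,
               p_value = t$p.value, n = paste(t$n, collapse = "/"))
  }))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end: obtain data (simulate, or read the
#' TSV inputs), build the leave-one-out control panel, score patients,
#' compare the dichotomized score with the CTC count (cross-tabulation
#' with discordance, Spearman, Jonckheere-Terpstra across CTC classes,
#' chi-square on the 2x2), and run the survival stage (Kaplan-Meier per
#' score class, log-rank, log-rank trend over combined-marker strata,
#' univariable and backward-stepwise Cox). All outputs are written under
#' \code{output_dir}; a run with the same configuration and seed
#' reproduces them exactly.
#'
#' @param config a validated configuration ([validateConfig()]), or a
#'   path/list to validate first.
#' @return invisibly, a run-report list (also written as
#'   \code{report.json} and \code{report.txt}).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "runConfig")) config <- validateConfig(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  report <- list(seed = config$seed, endpoint = config$endpoint)
  withCallingHandlers({
    if (!is.null(config$simulation)) {
      sim_args <- config$simulation
      sim_args$seed <- sim_args$seed %||% config$seed
      sim <- simulateCohort(do.call(simulationConfig, sim_args))
      controls <- sim$controls
      patients <- sim$patients
      clinical <- sim$clinical
      writeCountTable(controls, file.path(out, "control_counts.tsv"))
      writeCountTable(patients, file.path(out, "patient_counts.tsv"))
      write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    } else {
      arms <- if (is.null(config$inputs$arm_definitions))
        defaultArmDefinitions()
      else loadArmDefinitions(config$inputs$arm_definitions)
      controls <- readCountTable(config$inputs$control_counts, arms)
      patients <- readCountTable(config$inputs$patient_counts, arms)
      clinical <- read.delim(config$inputs$clinical)
    }
    report$n_controls <- length(sampleIds(controls))
    report$n_patients <- length(sampleIds(patients))

    stage <- "panel"
    panel <- buildPanel(normalizeToFractions(controls), loo = TRUE)
    savePanel(panel, file.path(out, "panel.json"))
    exportPanelTsv(panel, file.path(out, "panel_arms.tsv"))

    stage <- "score"
    res <- scoreSamples(normalizeToFractions(patients), panel,
                        cutoff = config$cutoffs$score)
    writeScoresTsv(res, file.path(out, "scores.tsv"),
                   file.path(out, "arm_calls.tsv"))
    report$n_score_high <- sum(scoreClasses(res) == "high")

    stage <- "compare"
    stopifnot(identical(clinical$patient_id, sampleIds(res)))
    scores <- aneuploidyScores(res)
    ctc <- clinical$ctc_count
    ok <- !is.na(ctc)
    if (any(!ok))
      message(sprintf("compare: excluded %d patient(s) without CTC count",
                      sum(!ok)))
    conc <- crossTabulate(scores[ok], ctc[ok],
                          cutoff = config$cutoffs$ctc)
    ctc_class <- cut(ctc[ok], c(-Inf, 0, config$cutoffs$ctc - 1, Inf),
                     labels = c("0", "intermediate", "high"))
    tests <- list(
      spearman_score_ctc = spearmanTest(scores[ok], ctc[ok]),
      jt_score_by_ctc_class = jonckheereTerpstra(
        split(scores[ok], ctc_class)[table(ctc_class) > 0]),
      chisq_score_ctc = chiSquare2x2(concordanceMatrix(conc)))
    if (!is.null(clinical$visceral))
      tests$mw_score_visceral <- mannWhitneyTest(
        scores[clinical$visceral == 1], scores[clinical$visceral == 0])
    write.table(tidyTests(tests), file.path(out, "association_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$concordance <- unclass(conc)
    report$discordance_pct <- discordanceRate(conc)
    report$tests <- lapply(tests, function(t)
      list(method = t$method, statistic = t$statistic, p = t$p.value))

    stage <- "survive"
    tcol <- paste0(config$endpoint, "_months")
    ecol <- paste0(config$endpoint, "_event")
    surv_df <- data.frame(
      time = clinical[[tcol]], event = clinical[[ecol]],
      score_high = as.integer(scores >= config$cutoffs$score),
      ctc_high = as.integer(ctc >= config$cutoffs$ctc),
      age = clinical$age, who_ps = factor(clinical$who_ps),
      visceral = clinical$visceral, dfi_months = clinical$dfi_months,
      cdk46i = clinical$cdk46i, ca153_high = clinical$ca153_high)
    km_low <- kaplanMeier(surv_df$time[surv_df$score_high == 0],
                          surv_df$event[surv_df$score_high == 0])
    km_high <- kaplanMeier(surv_df$time[surv_df$score_high == 1],
                           surv_df$event[surv_df$score_high == 1])
    writeKmTsv(km_low, file.path(out, "km_score_low.tsv"))
    writeKmTsv(km_high, file.path(out, "km_score_high.tsv"))
    lr <- logrankTest(surv_df$time, surv_df$event, surv_df$score_high)
    strata <- factor(surv_df$score_high + surv_df$ctc_high,
                     levels = 0:2,
                     labels = c("both_low", "one_high", "both_high"))
    lr_trend <- if (nlevels(droplevels(strata)) >= 2)
      logrankTrend(surv_df$time, surv_df$event, strata) else NULL
    candidates <- c("age", "who_ps", "dfi_months", "visceral", "cdk46i",
                    "ca153_high", "score_high", "ctc_high")
    candidates <- candidates[vapply(candidates, function(v)
      length(unique(surv_df[[v]])) > 1, logical(1))]
    sw <- stepwiseCox(surv_df, candidates)
    uni_rows <- do.call(rbind, lapply(candidates, function(v) {
      f <- coxFit(surv_df, v)
      cbind(f$terms, candidate = v, model = "univariable")
    }))
    multi_rows <- if (!is.null(sw$final))
      cbind(sw$final$terms, candidate = NA, model = "multivariable")
    else NULL
    write.table(rbind(uni_rows, multi_rows),
                file.path(out, "cox_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$km <- list(
      median_low = km_low$median, median_high = km_high$median)
    report$logrank_p <- lr$p.value
    report$logrank_trend_p <- if (!is.null(lr_trend)) lr_trend$p.value
    report$stepwise_selected <- sw$selected
    if (!is.null(sw$final)) {
      sc <- sw$final$terms[sw$final$terms$term == "score_high", ]
      if (nrow(sc))
        report$hr_score_class <- list(hr = sc$hr, ci_low = sc$ci_low,
                                      ci_high = sc$ci_high, p = sc$p)
    }
  }, error = function(e)
    stopf("pipeline failed at stage '%s': %s", stage,
          conditionMessage(e)))

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  writeLines(formatReport(report), file.path(out, "report.txt"))
  invisible(report)
}

formatReport <- function(r) {
  c("=== cfAneuploidy run report ===",
    sprintf("seed: %s  endpoint: %s", r$seed, toupper(r$endpoint)),
    sprintf("[cohort] %d controls, %d patients (%d score-high)",
            r$n_controls, r$n_patients, r$n_score_high),
    "[concordance]",
    sprintf("  both low %d, both high %d, CTC-only high %d, score-only high %d",
            r$concordance$n_low_low, r$concordance$n_high_high,
            r$concordance$n_ctc_only_high, r$concordance$n_score_only_high),
    sprintf("  discordance: %.1f%%", r$discordance_pct),
    "[association tests]",
    vapply(names(r$tests), function(nm)
      sprintf("  %s: statistic %.4g, p %.4g", nm, r$tests[[nm]]$statistic,
              r$tests[[nm]]$p), character(1)),
    "[survival]",
    sprintf("  median (score low/high): %.1f / %.1f months",
            r$km$median_low, r$km$median_high),
    sprintf("  log-rank p: %.4g; trend p: %s", r$logrank_p,
            if (is.null(r$logrank_trend_p)) "NA"
            else sprintf("%.4g", r$logrank_trend_p)),
    sprintf("  stepwise-selected: %s",
            paste(r$stepwise_selected, collapse = ", ")),
    if (!is.null(r$hr_score_class))
      sprintf("  score-class HR %.2f (95%% CI %.2f-%.2f), p %.3g",
              r$hr_score_class$hr, r$hr_score_class$ci_low,
              r$hr_score_class$ci_high, r$hr_score_class$p))
}

#' Report the printed-counts concordance worked example
#'
#' Convenience wrapper: build a concordance table directly from the four
#' cell counts and return the discordance rate together with the cell
#' percentages (one decimal).
#'
#' @inheritParams concordanceTable
#' @return list with \code{table}, \code{discordance_pct} and
#'   \code{cell_pct} (named: low_low, high_high, ctc_only_high,
#'   score_only_high).
#' @export
concordanceSummary <- function(n_low_low, n_high_high, n_ctc_only_high,
                               n_score_only_high) {
  tab <- concordanceTable(n_low_low, n_high_high, n_ctc_only_high,
                          n_score_only_high)
  list(table = tab, discordance_pct = discordanceRate(tab),
       cell_pct = round(100 * c(
         low_low = tab$n_low_low, high_high = tab$n_high_high,
         ctc_only_high = tab$n_ctc_only_high,
         score_only_high = tab$n_score_only_high) / tab$total, 1))
}
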