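#' Cohort-level critical-slowing-down analysis
#'
#' Runs the full inference chain on a labelled cohort dataset for one window
#' size and one cohort pair (failures vs controls): eligibility filtering,
#' optional age stratification of the controls, the per-record [csd_ews()]
#' fit, and every cohort-level comparison — proportions of significant
#' increases with two-proportion z-tests, tau summaries with Welch t-tests,
#' confusion metrics with the positive-tau ROC AUC, the combined
#' positive-tau strength comparison, and the six weighted logistic models
#' with deviance ANOVAs.
#'
#' @param data a `"cohort_data"` object ([generate_cohort()] or
#'   [read_dataset()]).
#' @param cohort_pair length-2 vector: case cohort, control cohort
#'   (default `c(1, 2)`).
#' @param window_len indicator window length in minutes (default 60).
#' @param alpha significance level (default 0.05).
#' @param kernel_sd detrending bandwidth in seconds (default 600).
#' @param min_duration eligibility threshold in seconds (default 7200).
#' @param stratify age-match the controls to the cases before testing
#'   (default `FALSE`; the synthetic generator draws ages identically across
#'   cohorts, so matching is a no-op in expectation).
#' @param seed seed for the stratification subsample (only used when
#'   `stratify = TRUE`).
#' @param alternative,correction passed to the per-record trend tests.
#' @param models logistic model ids to fit (default `1:6`; set `NULL` to
#'   skip).
#' @param combined_indicators which indicators enter the combined
#'   positive-tau strength: `"both"` (default) or `"autocorrelation"`.
#' @return Object of class `"csd_run"`; see Details. Main components:
#'   `outcomes` (one row per record and test), `counts`, `proportions`
#'   (with z-test columns), `tau_summary` (with Welch columns),
#'   `performance` (confusion metrics and AUC per variable/indicator),
#'   `combined` (strength t-test and AUC), `models`, `anovas`,
#'   `exclusions`, `design`.
#' @export
csd_cohort_analysis <- function(data, cohort_pair = c(1L, 2L),
                                window_len = 60, alpha = 0.05,
                                kernel_sd = 600, min_duration = 7200,
                                stratify = FALSE, seed = NULL,
                                alternative = "increase",
                                correction = "hamed_rao",
                                models = 1:6,
                                combined_indicators = c("both",
                                                        "autocorrelation")) {
  stopifnot(inherits(data, "cohort_data"), length(cohort_pair) == 2L)
  combined_indicators <- match.arg(combined_indicators)
  case_cohort <- cohort_pair[1L]; control_cohort <- cohort_pair[2L]
  records <- data$records[data$records$cohort %in% cohort_pair, ,
                          drop = FALSE]
  elig <- eligibility_filter(records, min_duration = min_duration)
  records <- elig$retained
  exclusions <- elig$excluded
  if (stratify) {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    cases <- records[records$cohort == case_cohort, , drop = FALSE]
    ctrls <- records[records$cohort == control_cohort, , drop = FALSE]
    matched <- stratify_match(cases, ctrls)
    dropped <- ctrls[!ctrls$patient_id %in% matched$patient_id, ,
                     drop = FALSE]
    if (nrow(dropped)) {
      dropped$reason <- "age stratification subsample"
      exclusions <- rbind(exclusions, dropped)
    }
    records <- rbind(cases, matched)
  }
  outcome_rows <- list()
  design_rows <- list()
  fit_failures <- character(0)
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    ser <- data$series[[rec$patient_id]]
    fit <- tryCatch(
      csd_ews(ser, dt = data$config$dt %||% 5, window_len = window_len,
              kernel_sd = kernel_sd, alpha = alpha,
              alternative = alternative, correction = correction),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit_failures <- c(fit_failures, rec$patient_id)
      next
    }
    t <- fit$tests
    t$patient_id <- rec$patient_id
    t$cohort <- rec$cohort
    t$ward <- rec$ward
    outcome_rows[[length(outcome_rows) + 1L]] <- t
    tau <- coef(fit)
    drow <- data.frame(patient_id = rec$patient_id,
                       outcome = as.integer(rec$cohort == case_cohort))
    for (v in c("HR", "RR", "ABP")) {
      drow[[paste0(v, "_r1_tau")]] <- unname(tau[paste0(v, "_r1")]) %|NA|% NA_real_
      drow[[paste0(v, "_var_tau")]] <- unname(tau[paste0(v, "_var")]) %|NA|% NA_real_
      drow[[paste0(v, "_mean")]] <- unname(fit$raw_means[v]) %|NA|% NA_real_
    }
    design_rows[[length(design_rows) + 1L]] <- drow
  }
  if (!length(outcome_rows)) stop("no record could be analyzed")
  outcomes <- do.call(rbind, outcome_rows)
  design <- do.call(rbind, design_rows)
  design$cohort <- records$cohort[match(design$patient_id,
                                        records$patient_id)]

  props <- proportion_table(outcomes)
  counts <- stats::reshape(
    props[props$indicator == "autocorrelation",
          c("cohort", "ward", "variable", "n")],
    idvar = c("ward", "variable"), timevar = "cohort", direction = "wide")

  # z-tests per (ward, variable, indicator) between the cohort pair
  props_z <- merge(
    props[props$cohort == case_cohort, ],
    props[props$cohort == control_cohort, ],
    by = c("ward", "variable", "indicator"),
    suffixes = c("_case", "_control"))
  zres <- mapply(function(k1, n1, k2, n2) {
    unlist(two_proportion_ztest(k1, n1, k2, n2, alternative = "greater"))
  }, props_z$k_case, props_z$n_case, props_z$k_control, props_z$n_control)
  props_z$z <- zres["z", ]
  props_z$p <- zres["p", ]

  # tau summaries and Welch t-tests per cell
  tau_cells <- expand.grid(ward = c(unique(outcomes$ward), "Whole"),
                           variable = unique(outcomes$variable),
                           indicator = c("variance", "autocorrelation"),
                           stringsAsFactors = FALSE)
  tau_rows <- lapply(seq_len(nrow(tau_cells)), function(j) {
    cell <- tau_cells[j, ]
    sel <- outcomes$variable == cell$variable &
      outcomes$indicator == cell$indicator &
      (cell$ward == "Whole" | outcomes$ward == cell$ward)
    t1 <- outcomes$tau[sel & outcomes$cohort == case_cohort]
    t2 <- outcomes$tau[sel & outcomes$cohort == control_cohort]
    out <- data.frame(cell,
                      mean_case = mean(t1), se_case = stats::sd(t1) /
                        sqrt(length(t1)),
                      n_case = length(t1),
                      mean_control = mean(t2), se_control = stats::sd(t2) /
                        sqrt(length(t2)),
                      n_control = length(t2),
                      t = NA_real_, df = NA_real_, p = NA_real_)
    if (length(t1) >= 2 && length(t2) >= 2 &&
        (stats::sd(t1) > 0 || stats::sd(t2) > 0)) {
      w <- welch_ttest(t1, t2, alternative = "two.sided")
      out$t <- w$t; out$df <- w$df; out$p <- w$p
    }
    out
  })
  tau_summary <- do.call(rbind, tau_rows)

  # confusion metrics + positive-tau ROC AUC per (variable, indicator)
  perf_rows <- list()
  for (v in unique(outcomes$variable)) {
    for (ind in c("variance", "autocorrelation")) {
      sel <- outcomes$variable == v & outcomes$indicator == ind
      if (!any(sel & outcomes$cohort == case_cohort) ||
          !any(sel & outcomes$cohort == control_cohort)) next
      cm <- confusion_and_metrics(outcomes, v, ind,
                                  case_cohort = case_cohort,
                                  control_cohort = control_cohort)
      roc <- roc_auc_positive_tau(outcomes$tau[sel],
                                  outcomes$cohort[sel] == case_cohort)
      perf_rows[[length(perf_rows) + 1L]] <- data.frame(
        variable = v, indicator = ind, tp = cm$tp, fp = cm$fp, fn = cm$fn,
        tn = cm$tn, ppv = cm$ppv, npv = cm$npv,
        sensitivity = cm$sensitivity, specificity = cm$specificity,
        balanced_accuracy = cm$balanced_accuracy, auc = roc$auc)
    }
  }
  performance <- do.call(rbind, perf_rows)

  # combined positive-tau strength across variables
  tau_cols <- if (combined_indicators == "both") {
    grep("_tau$", names(design), value = TRUE)
  } else {
    grep("_r1_tau$", names(design), value = TRUE)
  }
  strength <- apply(design[, tau_cols, drop = FALSE], 1L, function(r) {
    if (all(is.na(r))) NA_real_ else combined_strength(r)
  })
  s_case <- strength[design$outcome == 1 & !is.na(strength)]
  s_ctrl <- strength[design$outcome == 0 & !is.na(strength)]
  combined <- list(strength = strength)
  if (length(s_case) >= 2 && length(s_ctrl) >= 2) {
    combined$t_test <- welch_ttest(s_case, s_ctrl, alternative = "greater")
    combined$auc <- roc_auc_positive_tau(
      strength[!is.na(strength)],
      design$outcome[!is.na(strength)] == 1)$auc
  }

  fits <- list()
  anovas <- list()
  if (length(models) && all(c("HR", "RR", "ABP") %in%
                            unique(outcomes$variable))) {
    for (m in models) {
      fits[[as.character(m)]] <- tryCatch(fit_logistic(design, m),
                                          error = function(e) e)
    }
    ok <- function(m) inherits(fits[[as.character(m)]], "glm")
    if (all(vapply(c(4, 5, 6), ok, logical(1)))) {
      n4 <- fits[["4"]]$n; n5 <- fits[["5"]]$n; n6 <- fits[["6"]]$n
      if (n4 == n6) anovas$m4_vs_m6 <- anova_deviance(fits[["4"]],
                                                      fits[["6"]])
      if (n5 == n6) anovas$m5_vs_m6 <- anova_deviance(fits[["5"]],
                                                      fits[["6"]])
    }
  }

  structure(list(outcomes = outcomes, design = design, counts = counts,
                 proportions = props_z, tau_summary = tau_summary,
                 performance = performance, combined = combined,
                 models = fits, anovas = anovas,
                 exclusions = exclusions, fit_failures = fit_failures,
                 settings = list(cohort_pair = cohort_pair,
                                 window_len = window_len, alpha = alpha,
                                 kernel_sd = kernel_sd,
                                 min_duration = min_duration,
                                 stratify = stratify,
                                 alternative = alternative,
                                 correction = correction)),
            class = "csd_run")
}

`%|NA|%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @export
print.csd_run <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "CSD cohort analysis: cohort %d vs %d, %g-min windows, alpha %g\n",
    s$cohort_pair[1L], s$cohort_pair[2L], s$window_len, s$alpha))
  cat(sprintf("  records analyzed: %d (excluded: %d; fit failures: %d)\n",
              length(unique(x$outcomes$patient_id)), nrow(x$exclusions),
              length(x$fit_failures)))
  whole <- x$proportions[x$proportions$ward == "Whole", ]
  cat("  whole-cohort proportions of significant increases:\n")
  for (i in seq_len(nrow(whole))) {
    cat(sprintf("    %-3s %-15s case %.3f vs control %.3f (z = %.2f, p = %.3f)%s\n",
                whole$variable[i], whole$indicator[i],
                whole$proportion_case[i], whole$proportion_control[i],
                whole$z[i], whole$p[i],
                if (!is.na(whole$p[i]) && whole$p[i] <= s$alpha) " *" else ""))
  }
  if (!is.null(x$combined$t_test)) {
    cat(sprintf(
      "  combined positive-tau strength: t = %.3f, one-sided p = %.3f, AUC = %.3f\n",
      x$combined$t_test$t, x$combined$t_test$p, x$combined$auc))
  }
  invisible(x)
}

#' @export
summary.csd_run <- function(object, ...) object

#' Run configuration for the full pipeline
#'
#' @param seed global seed; drives dataset generation and any subsampling.
#' @param window_lens window lengths in minutes (default 60; add 30 and 15
#'   for the sensitivity analysis).
#' @param cohort_pairs list of case/control cohort pairs (default
#'   `list(c(1, 2))`).
#' @param alpha,kernel_sd,min_duration,stratify,alternative,correction see
#'   [csd_cohort_analysis()].
#' @param generator a [cohort_config()] for dataset generation (ignored when
#'   an existing dataset is supplied to [run_pipeline()]).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, window_lens = 60,
                       cohort_pairs = list(c(1L, 2L)), alpha = 0.05,
                       kernel_sd = 600, min_duration = 7200,
                       stratify = FALSE, alternative = "increase",
                       correction = "hamed_rao",
                       generator = cohort_config()) {
  stopifnot(alpha > 0, alpha < 1, all(window_lens > 0))
  structure(list(seed = seed, window_lens = window_lens,
                 cohort_pairs = cohort_pairs, alpha = alpha,
                 kernel_sd = kernel_sd, min_duration = min_duration,
                 stratify = stratify, alternative = alternative,
                 correction = correction, generator = generator),
            class = "run_config")
}

#' Execute the end-to-end pipeline
#'
#' Generates (or loads) a cohort dataset, then runs
#' [csd_cohort_analysis()] for every configured window length and cohort
#' pair. When `out_dir` is given, the report tables (counts, proportions,
#' tau summaries, performance) are written as CSV files and a JSON manifest
#' records the configuration, seed, and per-stage record counts, so that no
#' record is lost silently.
#'
#' @param config a [run_config()].
#' @param data optional pre-built `"cohort_data"`; default generates one
#'   from `config$generator` and `config$seed`.
#' @param out_dir optional report directory.
#' @return Named list of `"csd_run"` objects
#'   (`w<window>_c<case>v<control>`), with attributes `manifest` and
#'   `config`.
#' @export
run_pipeline <- function(config = run_config(), data = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(data)) {
    data <- generate_cohort(config$generator, seed = config$seed)
  }
  runs <- list()
  stage_counts <- list(input_records = nrow(data$records))
  for (w in config$window_lens) {
    for (pair in config$cohort_pairs) {
      key <- sprintf("w%g_c%dv%d", w, pair[1L], pair[2L])
      run <- csd_cohort_analysis(
        data, cohort_pair = pair, window_len = w, alpha = config$alpha,
        kernel_sd = config$kernel_sd, min_duration = config$min_duration,
        stratify = config$stratify, seed = config$seed,
        alternative = config$alternative, correction = config$correction)
      runs[[key]] <- run
      stage_counts[[key]] <- list(
        analyzed = length(unique(run$outcomes$patient_id)),
        excluded = nrow(run$exclusions),
        fit_failures = length(run$fit_failures))
    }
  }
  manifest <- list(seed = config$seed,
                   alpha = config$alpha,
                   window_lens = config$window_lens,
                   stage_counts = stage_counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(runs)) {
      run <- runs[[key]]
      for (tbl in c("counts", "proportions", "tau_summary", "performance")) {
        if (!is.null(run[[tbl]])) {
          utils::write.csv(run[[tbl]],
                           file.path(out_dir,
                                     sprintf("%s_%s.csv", key, tbl)),
                           row.names = FALSE)
        }
      }
      utils::write.csv(run$outcomes,
                       file.path(out_dir, sprintf("%s_outcomes.csv", key)),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  attr(runs, "manifest") <- manifest
  attr(runs, "config") <- config
  runs
}
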