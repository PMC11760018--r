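#' Fit the critical-slowing-down early-warning analysis to one record
#'
#' The central per-record fit. Takes the raw vital-sign series of a single
#' monitored extubation episode and runs the full per-record procedure:
#'
#' 1. gap handling ([handle_gaps()]): short missing runs filled from their
#'    endpoints, long runs spliced out;
#' 2. Gaussian detrending ([detrend_gaussian()]) and outlier replacement
#'    ([clip_outliers()]), leaving residual fluctuations;
#' 3. sliding-window variance and lag-1 autocorrelation traces
#'    ([compute_ews_trace()]);
#' 4. Hamed-Rao-corrected Mann-Kendall trend tests with Holm-Bonferroni
#'    correction across the record's tests ([evaluate_record()]).
#'
#' Variables whose series are too short after gap handling to support one
#' window are dropped from the family (recorded in `dropped`).
#'
#' @param series named list of raw numeric series (one per variable, e.g.
#'   `HR`, `RR`, `ABP`), `NA` marking missing samples, on a uniform grid.
#' @param dt sampling interval in seconds (default 5).
#' @param window_len indicator window length in minutes (default 60).
#' @param step window slide step in minutes (default 1).
#' @param kernel_sd detrending bandwidth in seconds (default 600).
#' @param max_fill_gap longest missing run (steps) filled rather than spliced
#'   (default 10).
#' @param alpha family-wise significance level (default 0.05).
#' @param alternative `"increase"` (default) or `"two.sided"`.
#' @param correction `"hamed_rao"` (default) or `"none"`.
#' @param detrend set `FALSE` to skip detrending (residuals already given).
#' @return Object of class `"csd_ews"`: list with `tests` (the
#'   [evaluate_record()] data frame), `traces`, `residuals`, `raw_means`
#'   (per-variable mean of the gap-handled raw series, used by the
#'   mean-based logistic models), `dropped`, `family_size`, `alpha`, `call`.
#' @examples
#' rec <- data.frame(cohort = 1L, duration_s = 7200)
#' sr <- simulate_record(rec, cohort_config(n_cohort = c(1L, 0L, 0L, 0L)))
#' fit <- csd_ews(sr)
#' fit
#' @export
csd_ews <- function(series, dt = 5, window_len = 60, step = 1,
                    kernel_sd = 600, max_fill_gap = 10L, alpha = 0.05,
                    alternative = "increase", correction = "hamed_rao",
                    detrend = TRUE) {
  if (!is.list(series) || is.null(names(series))) {
    stop("'series' must be a named list of per-variable series")
  }
  m_samples <- window_len * 60 / dt
  residuals <- list()
  traces <- list()
  raw_means <- c()
  dropped <- character(0)
  for (v in names(series)) {
    g <- tryCatch(handle_gaps(series[[v]], max_fill_gap = max_fill_gap),
                  error = function(e) NULL)
    if (is.null(g) || length(g) < m_samples) {
      dropped <- c(dropped, v)
      next
    }
    attr(g, "dt") <- dt
    attr(g, "variable") <- v
    raw_means[v] <- mean(g)
    r <- if (detrend) detrend_gaussian(g, kernel_sd = kernel_sd, dt = dt) else g
    r <- clip_outliers(r)
    residuals[[v]] <- r
    traces[[v]] <- compute_ews_trace(r, window_len = window_len, step = step,
                                     dt = dt)
  }
  if (!length(traces)) {
    stop("no variable has enough data for a single window")
  }
  tests <- evaluate_record(traces, alpha = alpha, alternative = alternative,
                           correction = correction)
  structure(list(tests = tests, traces = traces, residuals = residuals,
                 raw_means = raw_means, dropped = dropped,
                 family_size = attr(tests, "family_size"),
                 window_len = window_len, alpha = alpha,
                 call = match.call()),
            class = "csd_ews")
}

#' @export
print.csd_ews <- function(x, ...) {
  cat("Critical-slowing-down EWS fit (", x$window_len, "-min windows, alpha ",
      x$alpha, ")\n", sep = "")
  t <- x$tests
  cat(sprintf("  %d trend tests over %d variable(s)%s\n", nrow(t),
              length(x$traces),
              if (length(x$dropped))
                paste0("; dropped: ", paste(x$dropped, collapse = ", "))
              else ""))
  sig <- t[t$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("  significant increases (Holm-corrected):\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %s %s: tau = %.3f, p_holm = %.4g\n", sig$variable[i],
                  sig$indicator[i], sig$tau[i], sig$p_holm[i]))
    }
  } else {
    cat("  no significant increases after Holm correction\n")
  }
  invisible(x)
}

#' @export
summary.csd_ews <- function(object, ...) {
  t <- object$tests
  t$tau <- round(t$tau, 4)
  t$z <- round(t$z, 3)
  structure(list(tests = t, family_size = object$family_size,
                 dropped = object$dropped, alpha = object$alpha),
            class = "summary.csd_ews")
}

#' @export
print.summary.csd_ews <- function(x, ...) {
  cat("Per-record trend tests (family size", x$family_size, ", alpha",
      x$alpha, ")\n")
  print(x$tests[, c("variable", "indicator", "n", "tau", "z", "p", "p_holm",
                    "significant")], row.names = FALSE)
  if (length(x$dropped)) {
    cat("dropped variables:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Kendall tau coefficients of a fitted record
#'
#' @param object a [csd_ews()] fit.
#' @param ... unused.
#' @return Named numeric vector `<variable>_<indicator>` of Kendall tau
#'   values.
#' @export
coef.csd_ews <- function(object, ...) {
  t <- object$tests
  stats::setNames(t$tau,
                  paste(t$variable,
                        ifelse(t$indicator == "variance", "var", "r1"),
                        sep = "_"))
}

#' @export
plot.csd_ews <- function(x, variable = names(x$traces)[1L], ...) {
  plot(x$traces[[variable]], ...)
  invisible(x)
}
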