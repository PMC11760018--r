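#' Kendall S statistic and tau against time order
#'
#' For a trace observed in time order, \eqn{S = \sum_{i<j} \mathrm{sign}(x_j -
#' x_i)} counts concordant minus discordant pairs and \eqn{\tau = S /
#' \binom{n}{2}} (tau-a; ties in the continuous indicator traces are
#' measure-zero, so no tie adjustment is applied to tau itself).
#'
#' @param x numeric trace of length >= 2 in time order.
#' @return List with integer-valued `S` and `tau` in \[-1, 1\].
#' @examples
#' kendall_s_tau(c(1, 2, 3, 4))  # S = 6, tau = 1
#' @export
kendall_s_tau <- function(x) {
  n <- length(x)
  if (n < 2L) stop("trace must contain at least 2 values")
  d <- sign(outer(x, x, "-"))  # d[j, i] = sign(x_j - x_i)
  S <- sum(d[lower.tri(d)])
  list(S = S, tau = S / (n * (n - 1) / 2))
}

#' Mann-Kendall trend test with Hamed-Rao autocorrelation correction
#'
#' Tests an indicator trace for a monotone trend. Because the trace comes
#' from heavily overlapping windows, successive values are strongly serially
#' correlated and the classical Mann-Kendall variance of S is too small; the
#' Hamed-Rao correction inflates it by
#' \deqn{n/n^* = 1 + \frac{2}{n(n-1)(n-2)} \sum_{i=1}^{n-1}
#'   (n-i)(n-i-1)(n-i-2)\,\rho_s(i),}
#' where \eqn{\rho_s(i)} is the lag-i autocorrelation of the ranks of the
#' trace, summed over lags whose autocorrelation falls outside the 95% normal
#' band \eqn{\pm z_{0.975}/\sqrt{n}}. The factor is floored at 1 so the
#' correction never deflates the variance. The usual tie term is subtracted
#' from the uncorrected variance. The z statistic uses the standard
#' continuity correction: \eqn{z = (S - 1)/\sqrt{\mathrm{Var}(S)}} for
#' \eqn{S > 0}, 0 for \eqn{S = 0}, \eqn{(S + 1)/\sqrt{\mathrm{Var}(S)}} for
#' \eqn{S < 0}.
#'
#' For traces shorter than 10 points the rank-autocorrelation estimate is
#' meaningless and the test falls back to the uncorrected variance with a
#' warning. A constant trace yields `tau = 0`, `p = 1` by convention.
#'
#' @param x numeric trace in time order.
#' @param alpha significance level recorded in the result (default 0.05).
#' @param alternative `"increase"` (one-sided, the critical-slowing-down
#'   hypothesis; default) or `"two.sided"`.
#' @param correction `"hamed_rao"` (default) or `"none"`.
#' @return Object of class `"mk_trend"`: list with `n`, `S`, `tau`, `var_s`,
#'   `z`, `p`, `alternative`, `corrected`, `significant` (`p <= alpha` and,
#'   for increases, `tau > 0`).
#' @export
mk_test <- function(x, alpha = 0.05,
                    alternative = c("increase", "two.sided"),
                    correction = c("hamed_rao", "none")) {
  alternative <- match.arg(alternative)
  correction <- match.arg(correction)
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  if (n < 2L) stop("trace must contain at least 2 values")
  res <- list(n = n, alternative = alternative, alpha = alpha)
  if (length(unique(x)) == 1L) {
    res <- c(res, list(S = 0, tau = 0, var_s = 0, z = 0, p = 1,
                       corrected = FALSE, significant = FALSE))
    class(res) <- "mk_trend"
    return(res)
  }
  kt <- kendall_s_tau(x)
  ties <- table(x)
  ties <- ties[ties > 1L]
  tie_term <- sum(ties * (ties - 1) * (2 * ties + 5))
  var0 <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  corrected <- FALSE
  var_s <- var0
  if (correction == "hamed_rao") {
    if (n >= 10L) {
      rk <- rank(x)
      rho <- as.numeric(stats::acf(rk, lag.max = n - 1L,
                                   plot = FALSE)$acf)[-1L]
      lag <- seq_along(rho)
      sig <- abs(rho) > stats::qnorm(0.975) / sqrt(n)
      ssum <- sum(((n - lag) * (n - lag - 1) * (n - lag - 2) * rho)[sig])
      nf <- 1 + 2 / (n * (n - 1) * (n - 2)) * ssum
      var_s <- var0 * max(nf, 1)
      corrected <- TRUE
    } else {
      warning("trace shorter than 10 points; using uncorrected Mann-Kendall")
    }
  }
  z <- if (kt$S > 0) (kt$S - 1) / sqrt(var_s)
       else if (kt$S < 0) (kt$S + 1) / sqrt(var_s)
       else 0
  p <- switch(alternative,
              increase = stats::pnorm(z, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  p <- min(p, 1)
  significant <- p <= alpha && (alternative != "increase" || kt$tau > 0)
  res <- c(res, list(S = kt$S, tau = kt$tau, var_s = var_s, z = z, p = p,
                     corrected = corrected, significant = significant))
  class(res) <- "mk_trend"
  res
}

#' @export
print.mk_trend <- function(x, ...) {
  cat("Mann-Kendall trend test",
      if (x$corrected) "(Hamed-Rao corrected)" else "(uncorrected)", "\n")
  cat(sprintf("  n = %d, S = %g, tau = %.4f, Var(S) = %.4g\n",
              x$n, x$S, x$tau, x$var_s))
  cat(sprintf("  z = %.4f, %s p = %.4g\n", x$z,
              if (x$alternative == "increase") "one-sided (increase)"
              else "two-sided", x$p))
  invisible(x)
}

#' Holm-Bonferroni step-down rejection flags
#'
#' Sorts the p-values ascending and rejects \eqn{p_{(i)}} while
#' \eqn{p_{(i)} \le \alpha/(m - i + 1)}, stopping at the first failure;
#' controls the family-wise error rate at `alpha`. Implemented through
#' [stats::p.adjust()].
#'
#' @param p vector of p-values in \[0, 1\].
#' @param alpha family-wise significance level (default 0.05).
#' @return Logical rejection flags in the original order (empty for empty
#'   input).
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (!length(p)) return(logical(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm") <= alpha
}

#' Trend-test a record's indicator traces with family-wise correction
#'
#' Runs the corrected Mann-Kendall test on every available (variable,
#' indicator) trace of one record — up to 6 combinations for HR, RR, ABP
#' times variance and lag-1 autocorrelation — then applies Holm-Bonferroni
#' across the record's own family of tests. A combination is called a
#' significant increase when its Holm-adjusted p-value passes `alpha` *and*
#' its Kendall tau is positive.
#'
#' @param traces named list (per variable) of [compute_ews_trace()] results.
#' @param alpha family-wise significance level (default 0.05).
#' @param alternative passed to [mk_test()].
#' @param correction passed to [mk_test()].
#' @return Data frame with one row per (variable, indicator): `variable`,
#'   `indicator`, `n`, `S`, `tau`, `var_s`, `z`, `p`, `p_holm`,
#'   `significant`; attribute `family_size` gives the number of tests.
#' @export
evaluate_record <- function(traces, alpha = 0.05,
                            alternative = "increase",
                            correction = "hamed_rao") {
  if (!length(traces)) stop("at least one trace is required")
  rows <- list()
  for (v in names(traces)) {
    tr <- traces[[v]]
    for (ind in c("variance", "autocorrelation")) {
      vals <- if (ind == "variance") tr$variance else tr$lag1_ac
      vals <- vals[!is.na(vals)]
      if (length(vals) < 2L) next
      m <- mk_test(vals, alpha = alpha, alternative = alternative,
                   correction = correction)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, indicator = ind, n = m$n, S = m$S, tau = m$tau,
        var_s = m$var_s, z = m$z, p = m$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable traces in this record")
  rej <- holm_bonferroni(out$p, alpha = alpha)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out$significant <- rej & out$tau > 0
  attr(out, "family_size") <- nrow(out)
  out
}
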