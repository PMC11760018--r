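#' Weighted logistic regression of extubation outcome
#'
#' Fits one of the six predefined logistic models of extubation outcome
#' (1 = failure) by maximum weighted likelihood, with case weights of
#' `weight_failure` on failures and 1 on successes to offset the strong
#' class imbalance (default 10:1). Models:
#'
#' 1. `outcome ~ HR_r1_tau + HR_var_tau`
#' 2. `outcome ~ RR_r1_tau + RR_var_tau`
#' 3. `outcome ~ ABP_r1_tau + ABP_var_tau`
#' 4. all six tau predictors
#' 5. `outcome ~ HR_mean + RR_mean + ABP_mean`
#' 6. all six tau predictors plus the three means
#'
#' Rows with a missing value in any of the model's predictors are dropped
#' (complete cases), so the multivariable models use fewer records than the
#' single-variable ones. Fitting is by [stats::glm()]; a non-converged fit or
#' complete separation is reported through the `converged` field rather than
#' silently clipped. `n` is the unweighted row count.
#'
#' @param data design data frame with column `outcome` (0/1) and the
#'   predictors named above.
#' @param model_id model number 1-6, or a formula for a custom model.
#' @param weight_failure weight applied to failure rows (default 10).
#' @return Object of class `"csd_logit"` extending `"glm"`, with extra
#'   fields `model_id`, `n` (complete-case rows), `nagelkerke_r2`, and
#'   `weight_failure`.
#' @export
fit_logistic <- function(data, model_id = 1L, weight_failure = 10) {
  forms <- list(
    outcome ~ HR_r1_tau + HR_var_tau,
    outcome ~ RR_r1_tau + RR_var_tau,
    outcome ~ ABP_r1_tau + ABP_var_tau,
    outcome ~ HR_r1_tau + HR_var_tau + RR_r1_tau + RR_var_tau +
      ABP_r1_tau + ABP_var_tau,
    outcome ~ HR_mean + RR_mean + ABP_mean,
    outcome ~ HR_r1_tau + HR_var_tau + RR_r1_tau + RR_var_tau +
      ABP_r1_tau + ABP_var_tau + HR_mean + RR_mean + ABP_mean
  )
  f <- if (inherits(model_id, "formula")) model_id else {
    if (!model_id %in% 1:6) stop("'model_id' must be 1..6 or a formula")
    forms[[model_id]]
  }
  vars <- all.vars(f)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("design table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  if (!nrow(d)) stop("no complete-case rows for this model")
  d$.w <- ifelse(d[[vars[1L]]] == 1, weight_failure, 1)
  fit <- stats::glm(f, data = d, family = stats::binomial(), weights = .w)
  fit$model_id <- if (inherits(model_id, "formula")) NA_integer_ else model_id
  fit$n <- nrow(d)
  fit$weight_failure <- weight_failure
  fit$nagelkerke_r2 <- nagelkerke_r2(fit, n = nrow(d))
  class(fit) <- c("csd_logit", class(fit))
  fit
}

#' Nagelkerke pseudo-R-squared of a fitted logistic model
#'
#' \deqn{R^2 = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}},}
#' where \eqn{L_1} is the (weighted) likelihood of the fitted model and
#' \eqn{L_0} that of the intercept-only model refitted on the same rows and
#' weights. `n` defaults to the unweighted number of rows.
#'
#' @param fit a binomial [stats::glm()] fit.
#' @param n sample size used in the normalization (default: rows of the
#'   model frame).
#' @return Nagelkerke R-squared in \[0, 1\].
#' @export
nagelkerke_r2 <- function(fit, n = NULL) {
  mf <- stats::model.frame(fit)
  if (is.null(n)) n <- nrow(mf)
  w <- stats::weights(fit)
  if (is.null(w)) w <- rep(1, nrow(mf))
  mf$.w0 <- w
  null_fit <- stats::glm(stats::update(stats::formula(fit), . ~ 1),
                         data = mf, family = stats::binomial(),
                         weights = .w0)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null_fit))
  r2 <- (1 - exp(2 / n * (ll0 - ll1))) / (1 - exp(2 / n * ll0))
  max(0, min(1, r2))
}

#' @export
print.csd_logit <- function(x, ...) {
  cat("Weighted logistic model",
      if (!is.na(x$model_id)) paste0("#", x$model_id), "\n")
  cat(sprintf("  n = %d rows, failure weight %g, converged: %s\n", x$n,
              x$weight_failure, x$converged))
  co <- summary(x)$coefficients  # dispatches to summary.glm
  print(round(co, 4))
  cat(sprintf("  AIC %.1f   Nagelkerke R2 %.3f\n", stats::AIC(x),
              x$nagelkerke_r2))
  invisible(x)
}

#' Deviance comparison of two nested weighted logistic models
#'
#' Chi-square analysis of deviance between a nested and a full model fitted
#' on identical rows and weights: the deviance difference is referred to a
#' chi-square distribution on the difference in parameter count.
#'
#' @param fit_nested,fit_full fits from [fit_logistic()] (or `glm`); the
#'   nested model's terms must be a subset of the full model's, and both
#'   must use the same rows and weights.
#' @return List with `deviance_diff`, `df_diff`, `p`.
#' @export
anova_deviance <- function(fit_nested, fit_full) {
  t1 <- attr(stats::terms(fit_nested), "term.labels")
  t2 <- attr(stats::terms(fit_full), "term.labels")
  if (!all(t1 %in% t2)) stop("models are not nested")
  if (stats::nobs(fit_nested) != stats::nobs(fit_full)) {
    stop("models must be fitted on identical rows")
  }
  dev_diff <- stats::deviance(fit_nested) - stats::deviance(fit_full)
  df_diff <- fit_nested$df.residual - fit_full$df.residual
  p <- if (df_diff > 0) {
    stats::pchisq(dev_diff, df_diff, lower.tail = FALSE)
  } else 1
  list(deviance_diff = dev_diff, df_diff = df_diff, p = p)
}
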