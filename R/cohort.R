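#' Age-stratified subsampling of controls
#'
#' Matches the control cohort to the case cohort on a binned covariate
#' (age by default): the covariate is binned, and controls are randomly
#' subsampled within bins so the binned distribution matches the cases' bin
#' proportions. Sex is left unmatched and ward is handled by subgroup
#' analysis, not matching. If a bin holds cases but too few (or no)
#' controls, all available controls in that bin are taken with a warning.
#'
#' @param cases data frame of case records.
#' @param controls data frame of control records.
#' @param covariate column name to stratify on (default `"age"`).
#' @param n_bins number of quantile bins over the cases' covariate
#'   distribution (default 6); controls outside the cases' range are never
#'   selected.
#' @return Subset of `controls` whose binned covariate distribution matches
#'   the cases'.
#' @export
stratify_match <- function(cases, controls, covariate = "age", n_bins = 6L) {
  if (!nrow(cases) || !nrow(controls)) stop("both cohorts must be non-empty")
  # bins follow the cases' covariate distribution; controls outside the
  # cases' range fall in no bin and are never selected
  breaks <- unique(stats::quantile(cases[[covariate]],
                                   probs = seq(0, 1,
                                               length.out = n_bins + 1)))
  if (length(breaks) < 2L) breaks <- c(breaks, breaks + 1e-9)
  breaks[1L] <- -Inf
  case_bin <- cut(cases[[covariate]], breaks, include.lowest = TRUE)
  ctrl_bin <- cut(controls[[covariate]], breaks, include.lowest = TRUE)
  p_case <- table(case_bin) / nrow(cases)
  n_ctrl <- table(ctrl_bin)
  active <- names(p_case)[p_case > 0]
  covered <- active[n_ctrl[active] > 0]
  if (length(covered) < length(active)) {
    warning("no controls available in bins: ",
            paste(setdiff(active, covered), collapse = ", "))
  }
  # largest total size that respects every covered bin's availability
  n_total <- floor(min(n_ctrl[covered] / p_case[covered]))
  take <- integer(0)
  for (b in active) {
    want <- round(p_case[[b]] * n_total)
    avail <- which(as.character(ctrl_bin) == b)
    if (length(avail) < want) {
      warning(sprintf("bin %s: only %d controls for a target of %d", b,
                      length(avail), want))
      want <- length(avail)
    }
    take <- c(take, avail[sample.int(length(avail), want)])
  }
  controls[sort(take), , drop = FALSE]
}

#' Proportions of significant increases per cohort cell
#'
#' Aggregates per-record trend outcomes into proportions of records showing a
#' significant increase, per (cohort, ward, variable, indicator), with a
#' whole-cohort row per (cohort, variable, indicator).
#'
#' @param outcomes data frame with columns `cohort`, `ward`, `variable`,
#'   `indicator`, `significant` (one row per record and test).
#' @return Data frame with columns `cohort`, `ward` (including `"Whole"`),
#'   `variable`, `indicator`, `k` (significant count), `n` (evaluable
#'   count), `proportion` (`NA` when `n` is 0).
#' @export
proportion_table <- function(outcomes) {
  whole <- outcomes
  whole$ward <- "Whole"
  both <- rbind(outcomes, whole)
  agg <- stats::aggregate(cbind(k = significant, n = 1L) ~
                            cohort + ward + variable + indicator,
                          data = transform(both, significant =
                                             as.integer(significant)),
                          FUN = sum)
  agg$proportion <- ifelse(agg$n > 0, agg$k / agg$n, NA_real_)
  agg[order(agg$cohort, agg$ward, agg$variable, agg$indicator), ]
}

#' Two-proportion z-test with pooled variance
#'
#' \deqn{z = \frac{k_1/n_1 - k_2/n_2}
#'   {\sqrt{\hat p (1 - \hat p)(1/n_1 + 1/n_2)}}, \quad
#'   \hat p = \frac{k_1 + k_2}{n_1 + n_2}.}
#' Used to compare the proportion of significant increases between the
#' failure and control cohorts. When the pooled proportion is 0 or 1 the
#' test is degenerate and `p = 1` is returned.
#'
#' @param k1,n1 significant count and evaluable size in group 1.
#' @param k2,n2 the same for group 2.
#' @param alternative `"greater"` (group 1 larger; default, the
#'   critical-slowing-down hypothesis) or `"two.sided"`.
#' @return List with `z` and `p`.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  p_hat <- (k1 + k2) / (n1 + n2)
  if (p_hat <= 0 || p_hat >= 1) return(list(z = 0, p = 1))
  z <- (k1 / n1 - k2 / n2) /
    sqrt(p_hat * (1 - p_hat) * (1 / n1 + 1 / n2))
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(z = z, p = min(p, 1))
}

#' Welch's t-test from samples or summary statistics
#'
#' Compares the means of two tau distributions without assuming equal
#' variances: \eqn{t = (m_1 - m_2)/\sqrt{se_1^2 + se_2^2}} with
#' Welch-Satterthwaite degrees of freedom
#' \deqn{\nu = \frac{(se_1^2 + se_2^2)^2}
#'   {se_1^4/(n_1 - 1) + se_2^4/(n_2 - 1)}.}
#' Accepts either two numeric samples, or the summary form
#' `list(mean =, se =, n =)` for each group (as printed in cohort summary
#' tables).
#'
#' @param x,y numeric samples, or lists with `mean`, `se`, `n`.
#' @param alternative `"two.sided"` (default), `"greater"` (mean of `x`
#'   larger) or `"less"`.
#' @return List with `t`, `df`, `p`, and the group summaries.
#' @export
welch_ttest <- function(x, y, alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  summ <- function(a) {
    if (is.list(a)) {
      stopifnot(all(c("mean", "se", "n") %in% names(a)))
      a
    } else {
      a <- a[!is.na(a)]
      if (length(a) < 2L) stop("each sample needs at least 2 values")
      list(mean = mean(a), se = stats::sd(a) / sqrt(length(a)),
           n = length(a))
    }
  }
  s1 <- summ(x); s2 <- summ(y)
  if (s1$n < 2 || s2$n < 2) stop("group sizes must be >= 2")
  v <- s1$se^2 + s2$se^2
  if (v <= 0) stop("zero pooled standard error")
  t <- (s1$mean - s2$mean) / sqrt(v)
  df <- v^2 / (s1$se^4 / (s1$n - 1) + s2$se^4 / (s2$n - 1))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df))
  list(t = t, df = df, p = p, group1 = s1, group2 = s2,
       alternative = alternative)
}

#' Confusion matrix and classification metrics
#'
#' Treats extubation failure as the positive class and "significant increase
#' detected" as the positive prediction. Metrics: PPV = TP/(TP+FP), NPV =
#' TN/(TN+FN), sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), balanced
#' accuracy = (sensitivity + specificity)/2. A zero denominator yields `NA`
#' for that metric.
#'
#' @param tp,fp,fn,tn non-negative confusion counts.
#' @return List of class `"csd_metrics"`: the four counts plus `ppv`, `npv`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`.
#' @examples
#' classification_metrics(24, 253, 77, 1222)
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  sdiv <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- sdiv(tp, tp + fn)
  spec <- sdiv(tn, tn + fp)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 ppv = sdiv(tp, tp + fp), npv = sdiv(tn, tn + fn),
                 sensitivity = sens, specificity = spec,
                 balanced_accuracy = mean(c(sens, spec))),
            class = "csd_metrics")
}

#' @export
print.csd_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("PPV %.3f  NPV %.3f  Sens %.3f  Spec %.3f  Acc_B %.3f\n",
              x$ppv, x$npv, x$sensitivity, x$specificity,
              x$balanced_accuracy))
  invisible(x)
}

#' Confusion matrix from per-record outcomes
#'
#' @param outcomes data frame with `cohort`, `variable`, `indicator`,
#'   `significant`.
#' @param variable,indicator the (variable, indicator) pair to score.
#' @param case_cohort,control_cohort cohort labels of the positive and
#'   negative classes (defaults 1 and 2).
#' @return A [classification_metrics()] object.
#' @export
confusion_and_metrics <- function(outcomes, variable, indicator,
                                  case_cohort = 1L, control_cohort = 2L) {
  sel <- outcomes$variable == variable & outcomes$indicator == indicator
  ca <- outcomes[sel & outcomes$cohort == case_cohort, ]
  co <- outcomes[sel & outcomes$cohort == control_cohort, ]
  if (!nrow(ca) || !nrow(co)) stop("both cohorts must be present")
  classification_metrics(tp = sum(ca$significant),
                         fn = sum(!ca$significant),
                         fp = sum(co$significant),
                         tn = sum(!co$significant))
}

#' ROC curve and AUC under the positive-tau convention
#'
#' Scores each record by its Kendall tau, but first maps every non-positive
#' tau to a sentinel below all thresholds: only positive trends are allowed
#' to predict failure, so records with tau <= 0 are never classified
#' positive. Thresholds sweep the observed positive tau values (plus
#' extremes), the curve is completed to (1, 1), and the AUC is the trapezoid
#' area over (FPR, TPR). With no positive tau at all the curve is the chance
#' diagonal and the AUC is 0.5.
#'
#' @param tau per-record tau values.
#' @param labels logical (or 0/1) failure flags, same length.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc_positive_tau <- function(tau, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(tau) & !is.na(labels)
  tau <- tau[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels)) stop("both classes must be present")
  score <- ifelse(tau > 0, tau, -Inf)
  thr <- c(Inf, sort(unique(score[is.finite(score)]), decreasing = TRUE))
  pts <- vapply(thr, function(th) {
    pred <- score >= th
    c(fpr = sum(pred & !labels) / sum(!labels),
      tpr = sum(pred & labels) / sum(labels))
  }, c(fpr = 0, tpr = 0))
  roc <- data.frame(threshold = thr, fpr = pts["fpr", ], tpr = pts["tpr", ])
  roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  o <- order(roc$fpr, roc$tpr)
  fpr <- roc$fpr[o]; tpr <- roc$tpr[o]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Combined strength of positive trends across variables
#'
#' Per record, the sum of the positive parts of its Kendall tau coefficients
#' over the available (variable, indicator) combinations: negative trends
#' contribute nothing. Used as a single cross-variable score of how strongly
#' the record expresses critical slowing down.
#'
#' @param taus numeric tau values of one record (`NA` allowed).
#' @return Non-negative scalar.
#' @export
combined_strength <- function(taus) {
  if (!length(taus)) stop("at least one tau is required")
  sum(pmax(taus, 0), na.rm = TRUE)
}
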