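test_that("classification metrics reproduce hand-computed values", {
  m <- classification_metrics(24, 253, 77, 1222)
  expect_equal(m$ppv, 24 / 277)
  expect_equal(m$sensitivity, 24 / 101)
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
  perfect <- classification_metrics(10, 0, 0, 20)
  expect_equal(unlist(perfect[c("ppv", "npv", "sensitivity", "specificity",
                                "balanced_accuracy")]),
               c(ppv = 1, npv = 1, sensitivity = 1, specificity = 1,
                 balanced_accuracy = 1))
  degen <- classification_metrics(0, 0, 5, 10)
  expect_true(is.na(degen$ppv))
  expect_equal(degen$specificity, 1)
  expect_error(classification_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("two-proportion z-test matches the pooled closed form", {
  z <- two_proportion_ztest(24, 101, 253, 1475)
  p1 <- 24 / 101; p2 <- 253 / 1475; ph <- 277 / 1576
  expect_equal(z$z, (p1 - p2) / sqrt(ph * (1 - ph) * (1 / 101 + 1 / 1475)))
  expect_lt(z$p, 0.05)  # the one cell the study flags significant
  expect_equal(two_proportion_ztest(5, 50, 5, 50)$z, 0)
  expect_equal(two_proportion_ztest(5, 50, 5, 50)$p, 0.5)
  expect_equal(two_proportion_ztest(0, 50, 0, 60)$p, 1)
  expect_error(two_proportion_ztest(1, 0, 1, 10), "positive")
})

test_that("Welch t-test agrees with t.test on samples and handles the
           summary form", {
  set.seed(20)
  for (k in 1:20) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 2))
    got <- welch_ttest(x, y)
    want <- t.test(x, y)
    expect_equal(got$t, unname(want$statistic))
    expect_equal(got$df, unname(want$parameter))
    expect_equal(got$p, want$p.value)
    one <- welch_ttest(x, y, alternative = "greater")
    wone <- t.test(x, y, alternative = "greater")
    expect_equal(one$p, wone$p.value)
  }
  ident <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(welch_ttest(rep(1, 5), rep(1, 5)), "zero pooled")
})

test_that("Welch p-values are uniform under the null", {
  set.seed(21)
  ps <- replicate(400, welch_ttest(rnorm(30), rnorm(25))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("positive-tau ROC handles separation, chance, and degeneracy", {
  # complete separation with all-positive taus
  r <- roc_auc_positive_tau(c(0.8, 0.7, 0.3, 0.2), c(TRUE, TRUE, FALSE,
                                                     FALSE))
  expect_equal(r$auc, 1)
  # all taus negative: single operating point, chance AUC by construction
  r0 <- roc_auc_positive_tau(c(-0.1, -0.5, -0.3), c(TRUE, FALSE, FALSE))
  expect_equal(r0$auc, 0.5)
  # permuted labels give chance-level AUC on average
  set.seed(22)
  aucs <- replicate(200, {
    tau <- rnorm(60, 0, 0.3)
    roc_auc_positive_tau(tau, sample(rep(c(TRUE, FALSE), 30)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  # invariance under strictly monotone transforms of the positive taus
  tau <- c(0.5, 0.2, -0.3, 0.1, -0.2, 0.4)
  lab <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  a1 <- roc_auc_positive_tau(tau, lab)$auc
  tau2 <- ifelse(tau > 0, tau^3, tau)
  expect_equal(roc_auc_positive_tau(tau2, lab)$auc, a1)
  expect_error(roc_auc_positive_tau(c(0.1, 0.2), c(TRUE, TRUE)),
               "both classes")
})

test_that("positive-tau ROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  tau <- c(runif(40, 0.01, 0.9), runif(40, -0.9, 0.9))
  lab <- c(rep(TRUE, 40), rep(FALSE, 40))
  score <- ifelse(tau > 0, tau, 0)  # shared sentinel below every threshold
  want <- as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE,
                                         direction = "<")))
  got <- roc_auc_positive_tau(tau, lab)$auc
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("combined strength sums only positive taus", {
  expect_equal(combined_strength(c(0.2, -0.5, 0.1)), 0.3)
  expect_equal(combined_strength(c(-0.2, -0.5)), 0)
  expect_equal(combined_strength(c(0.2, NA, 0.3)), 0.5)
  expect_error(combined_strength(numeric(0)), "at least one")
})

test_that("age stratification matches the case bin distribution", {
  set.seed(24)
  cases <- data.frame(patient_id = paste0("c", 1:60),
                      age = runif(60, 0, 1))  # all infants
  controls <- data.frame(patient_id = paste0("k", 1:600),
                         age = runif(600, 0, 18))
  matched <- stratify_match(cases, controls, n_bins = 4)
  expect_true(all(matched$age < 1 + 1e-9))
  # identical distributions: matched set stays large and balanced
  controls2 <- data.frame(patient_id = paste0("m", 1:600),
                          age = runif(600, 0, 1))
  matched2 <- stratify_match(cases, controls2, n_bins = 4)
  expect_gt(nrow(matched2), 300)
  # chi-square on binned ages: not significant across repeated seeds
  ps <- replicate(20, {
    m <- stratify_match(cases, controls, n_bins = 4)
    br <- c(-Inf, quantile(c(cases$age, m$age), c(0.25, 0.5, 0.75)), Inf)
    suppressWarnings(chisq.test(
      rbind(table(cut(cases$age, br)), table(cut(m$age, br))))$p.value)
  })
  expect_gt(mean(ps > 0.05), 0.8)
  expect_error(stratify_match(cases[0, ], controls), "non-empty")
})

test_that("proportion table aggregates per cell with whole-cohort rows", {
  outcomes <- data.frame(
    patient_id = rep(c("a", "b", "c", "d"), each = 2),
    cohort = rep(c(1, 1, 2, 2), each = 2),
    ward = rep(c("PICU", "CICU", "PICU", "CICU"), each = 2),
    variable = "HR",
    indicator = rep(c("variance", "autocorrelation"), 4),
    significant = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  tab <- proportion_table(outcomes)
  whole_var <- tab[tab$ward == "Whole" & tab$indicator == "variance", ]
  expect_equal(whole_var$proportion[whole_var$cohort == 1], 0.5)
  expect_equal(whole_var$k[whole_var$cohort == 2], 1)
  expect_equal(whole_var$n[whole_var$cohort == 2], 2)
})
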