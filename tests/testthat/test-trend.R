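test_that("Kendall S and tau match a brute-force all-pairs oracle", {
  expect_equal(kendall_s_tau(c(1, 2, 3, 4)), list(S = 6, tau = 1))
  expect_equal(kendall_s_tau(c(3, 1, 2)), list(S = -1, tau = -1 / 3))
  set.seed(12)
  for (k in 1:100) {
    n <- sample(3:40, 1)
    x <- if (k %% 4 == 0) sample(1:5, n, replace = TRUE) else rnorm(n)
    got <- kendall_s_tau(x)
    expect_identical(got$S, oracle_kendall_S(x))
    expect_equal(got$tau, got$S / (n * (n - 1) / 2))
    # antisymmetry under time reversal
    expect_equal(kendall_s_tau(rev(x))$S, -got$S)
  }
  expect_error(kendall_s_tau(1), "at least 2")
})

test_that("Kendall tau agrees with the base-R rank correlation on
           tie-free traces", {
  set.seed(13)
  for (k in 1:20) {
    x <- rnorm(sample(10:60, 1))
    expect_equal(kendall_s_tau(x)$tau,
                 cor(x, seq_along(x), method = "kendall"))
  }
})

test_that("Mann-Kendall degenerate and perfect-trend behaviour", {
  m <- mk_test(rep(1, 20))
  expect_equal(m$tau, 0)
  expect_equal(m$p, 1)
  expect_false(m$significant)
  # a perfect trend: overwhelming uncorrected; still clearly significant
  # under the Hamed-Rao correction, whose variance inflation saturates the
  # p-value near 1e-3 for fully rank-autocorrelated traces
  m0 <- mk_test(1:20, correction = "none")
  expect_equal(m0$tau, 1)
  expect_lt(m0$p, 1e-3)
  m <- mk_test(1:20)
  expect_equal(m$tau, 1)
  expect_lt(m$p, 0.01)
  expect_true(m$significant)
  # reversal flips the sign and kills the one-sided increase p
  m <- mk_test(20:1)
  expect_equal(m$tau, -1)
  expect_gt(m$p, 0.99)
  expect_warning(mk_test(rnorm(8)), "shorter than 10")
})

test_that("uncorrected Mann-Kendall holds its one-sided size on white
           noise", {
  set.seed(14)
  n_rep <- 2000
  rej <- replicate(n_rep, mk_test(rnorm(30), correction = "none")$p <= 0.05)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(mean(rej), 0.05 + 3 * se)
  expect_gt(mean(rej), 0.05 - 3 * se)
})

test_that("the Hamed-Rao correction reins in false positives on
           autocorrelated stationary traces", {
  set.seed(15)
  n_rep <- 500
  res <- t(replicate(n_rep, {
    x <- sim_ar1(80, phi = 0.8)
    c(corrected = mk_test(x)$p <= 0.05,
      plain = mk_test(x, correction = "none")$p <= 0.05)
  }))
  rate_corr <- mean(res[, "corrected"])
  rate_plain <- mean(res[, "plain"])
  expect_lte(rate_corr, rate_plain)
  # the uncorrected test is badly oversized here; the corrected one is the
  # point of the method
  expect_gt(rate_plain, 0.15)
  expect_lt(rate_corr, 0.15)
})

test_that("Holm-Bonferroni matches a literal step-down execution", {
  p <- c(0.001, 0.02, 0.03, 0.04, 0.2, 0.9)
  expect_equal(holm_bonferroni(p), oracle_holm(p))
  expect_equal(sum(holm_bonferroni(p)), 1)  # only 0.001 survives
  expect_equal(holm_bonferroni(rep(1, 6)), rep(FALSE, 6))
  expect_equal(holm_bonferroni(0.04), TRUE)  # single test: plain alpha
  expect_equal(holm_bonferroni(numeric(0)), logical(0))
  set.seed(16)
  for (k in 1:50) {
    p <- runif(sample(1:10, 1))^sample(1:3, 1)
    expect_equal(holm_bonferroni(p, 0.05), oracle_holm(p, 0.05))
  }
})

test_that("Holm sits between Bonferroni and uncorrected testing", {
  set.seed(17)
  for (k in 1:30) {
    p <- runif(6)^2
    holm <- holm_bonferroni(p)
    bonf <- p <= 0.05 / length(p)
    raw <- p <= 0.05
    expect_true(all(bonf[holm] | TRUE))      # sanity: same length
    expect_true(all(holm[bonf]))             # Bonferroni subset of Holm
    expect_true(all(raw[holm]))              # Holm subset of uncorrected
  }
})

test_that("evaluate_record tests each trace and corrects within the
           record's family", {
  set.seed(18)
  # one perfectly increasing variance trace among flat-noise traces
  mk_trace <- function(vals) {
    tr <- data.frame(t_start_s = seq_along(vals) * 60 - 60,
                     variance = vals,
                     lag1_ac = rnorm(length(vals), 0, 0.01))
    class(tr) <- c("ews_trace", "data.frame")
    tr
  }
  traces <- list(HR = mk_trace(seq(1, 2, length.out = 60)),
                 RR = mk_trace(rnorm(60)),
                 ABP = mk_trace(rnorm(60)))
  out <- evaluate_record(traces)
  expect_equal(attr(out, "family_size"), 6)
  hr_var <- out$variable == "HR" & out$indicator == "variance"
  expect_true(out$significant[hr_var])
  expect_false(any(out$significant[!hr_var]))
  # only HR available: family of 2
  out2 <- evaluate_record(traces["HR"])
  expect_equal(attr(out2, "family_size"), 2)
  expect_error(evaluate_record(list()), "at least one")
})

test_that("csd_ews fits a full record and exposes coefficients", {
  set.seed(19)
  rec <- data.frame(cohort = 1L, duration_s = 3 * 3600)
  sr <- simulate_record(rec, cohort_config())
  fit <- csd_ews(sr)
  expect_s3_class(fit, "csd_ews")
  expect_equal(fit$family_size, nrow(fit$tests))
  expect_true(all(abs(fit$tests$tau) <= 1))
  co <- coef(fit)
  expect_named(co)
  expect_true(all(grepl("_(var|r1)$", names(co))))
  expect_output(print(fit), "trend tests")
  expect_output(print(summary(fit)), "family size")
  # a strongly ramped record should flag significant increases
  expect_gt(sum(fit$tests$significant), 0)
})
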