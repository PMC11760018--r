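test_that("pseudo-duration sampling reproduces the source distribution", {
  expect_equal(sample_pseudo_duration(7200, 5), rep(7200, 5))
  set.seed(1)
  src <- rlnorm(100, log(4 * 3600), 0.5)
  draws <- sample_pseudo_duration(src, 10000)
  expect_true(all(draws %in% src))
  ks <- suppressWarnings(ks.test(draws, src))
  expect_gt(ks$p.value, 0.05)
  expect_error(sample_pseudo_duration(numeric(0)), "non-empty")
  set.seed(9); a <- sample_pseudo_duration(src, 50)
  set.seed(9); b <- sample_pseudo_duration(src, 50)
  expect_identical(a, b)
})

test_that("simulate_record realizes ramps for failures, constants for
           controls, and honours the gap specification", {
  cfg <- cohort_config(n_cohort = c(1L, 1L, 0L, 0L), gap_rate = 0)
  rec1 <- data.frame(cohort = 1L, duration_s = 7200)
  set.seed(2)
  sr <- simulate_record(rec1, cfg)
  expect_named(sr, c("HR", "RR", "ABP"))
  expect_true(all(vapply(sr, function(x) !anyNA(x), logical(1))))
  expect_equal(length(sr$HR), 7200 / 5 + 1)

  # with gaps switched on, missing runs appear
  cfg_gap <- cohort_config(gap_rate = 0.01)
  set.seed(3)
  sg <- simulate_record(rec1, cfg_gap)
  expect_true(anyNA(sg$HR))

  # ramped failure records end with visibly larger fluctuations than they
  # start with (variance grows as lam falls toward lam_end)
  set.seed(4)
  long_rec <- data.frame(cohort = 1L, duration_s = 6 * 3600)
  sf <- simulate_record(long_rec, cohort_config(gap_rate = 0))
  hr <- as.numeric(sf$HR)
  n <- length(hr)
  v_early <- var(hr[1:720])
  v_late <- var(hr[(n - 719):n])
  expect_gt(v_late, 3 * v_early)
})

test_that("control records show no systematic indicator trend", {
  # mean Kendall tau of the variance trace over many stationary records
  # should sit within 2 standard errors of zero
  set.seed(10)
  taus <- replicate(200, {
    x <- simulate_ou(1452, lam = 0.5, sigma = 1, dt = 5)
    tr <- compute_ews_trace(x)
    kendall_s_tau(tr$variance)$tau
  })
  expect_lt(abs(mean(taus)), 2 * sd(taus) / sqrt(length(taus)))
})

test_that("ramped records are detected with high power", {
  set.seed(11)
  hits <- replicate(60, {
    lam <- ramp_schedule(1452, 0.5, 0.005)
    x <- simulate_ou(1452, lam = lam, sigma = 1, dt = 5)
    tr <- compute_ews_trace(x)
    v <- mk_test(tr$variance)
    r <- mk_test(tr$lag1_ac[!is.na(tr$lag1_ac)])
    v$tau > 0 && r$tau > 0
  })
  expect_gt(mean(hits), 0.9)
})

test_that("generate_cohort produces the requested sizes and metadata
           invariants", {
  cfg <- cohort_config(n_cohort = c(5L, 12L, 2L, 1L),
                       duration_meanlog = log(2.2 * 3600),
                       duration_sdlog = 0.2, duration_max = 3 * 3600)
  d <- generate_cohort(cfg, seed = 3)
  expect_equal(tabulate(d$records$cohort, 4), c(5, 12, 2, 1))
  expect_true(all(d$records$endpoint_time > d$records$extubation_time))
  expect_true(all(d$records$duration_s >= 7200))
  expect_true(all(d$records$death_flag == (d$records$cohort %in% c(3, 4))))
  # control durations are resampled from the failure durations
  dur1 <- d$records$duration_s[d$records$cohort == 1]
  dur2 <- d$records$duration_s[d$records$cohort == 2]
  expect_true(all(dur2 %in% dur1))
  # a control-only dataset is valid
  d0 <- generate_cohort(cohort_config(n_cohort = c(0L, 4L, 0L, 0L),
                                      duration_max = 3 * 3600), seed = 4)
  expect_equal(nrow(d0$records), 4)
})

test_that("dataset generation is deterministic and round-trips through
           disk byte-identically", {
  cfg <- cohort_config(n_cohort = c(2L, 3L, 0L, 0L),
                       duration_meanlog = log(2.1 * 3600),
                       duration_sdlog = 0.1, duration_max = 3 * 3600)
  d1 <- withr::with_tempdir({
    generate_cohort_dataset(cfg, dir = "a", seed = 21)
    generate_cohort_dataset(cfg, dir = "b", seed = 21)
    fa <- sort(list.files("a", recursive = TRUE))
    fb <- sort(list.files("b", recursive = TRUE))
    expect_identical(fa, fb)
    for (f in fa) {
      expect_identical(readLines(file.path("a", f)),
                       readLines(file.path("b", f)))
    }
    read_dataset("a")
  })
  d2 <- generate_cohort(cfg, seed = 21)
  expect_equal(d1$records$patient_id, d2$records$patient_id)
  expect_equal(d1$records$duration_s, d2$records$duration_s)
  for (pid in d2$records$patient_id) {
    for (v in cfg$variables) {
      expect_equal(as.numeric(d1$series[[pid]][[v]]),
                   as.numeric(d2$series[[pid]][[v]]), tolerance = 1e-12)
    }
  }
})

test_that("read_dataset validates its inputs", {
  cfg <- cohort_config(n_cohort = c(1L, 1L, 0L, 0L),
                       duration_meanlog = log(2.1 * 3600),
                       duration_sdlog = 0.1, duration_max = 3 * 3600)
  withr::with_tempdir({
    generate_cohort_dataset(cfg, dir = "ds", seed = 5)
    # corrupt one series to a non-uniform grid
    f <- list.files("ds/series", full.names = TRUE)[1]
    df <- read.csv(f)
    df$time_s[3] <- df$time_s[3] + 1
    write.csv(df, f, row.names = FALSE, na = "")
    expect_error(read_dataset("ds"), "non-uniform")
    # restore, then delete a series file: record kept, variable unavailable
    generate_cohort_dataset(cfg, dir = "ds2", seed = 5)
    f2 <- list.files("ds2/series", full.names = TRUE)[1]
    unlink(f2)
    expect_warning(d <- read_dataset("ds2"), "unavailable")
    expect_equal(nrow(d$records), 2)
    # duplicate patient ids are rejected
    meta <- read.csv("ds2/metadata.csv")
    meta$patient_id <- meta$patient_id[1]
    write.csv(meta, "ds2/metadata.csv", row.names = FALSE)
    expect_error(read_dataset("ds2"), "duplicate")
  })
})
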