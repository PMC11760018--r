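#' Configuration for the synthetic extubation cohort generator
#'
#' Returns the default generator settings, optionally overridden through
#' `...`. The generator emulates the structure of post-extubation monitor
#' data: heart rate (HR, BPM), respiratory rate (RR, BrPM) and mean blood
#' pressure (ABP, mmHg) sampled every 5 seconds between extubation and an
#' endpoint (re-intubation, pseudo-re-intubation, or death), with a slowly
#' drifting baseline, OU residual fluctuations, and injected gaps of missing
#' samples. Failure records (cohort 1, and cohort 4 when requested) carry a
#' decay-rate ramp that reaches `lam_end` exactly at the endpoint — the
#' critical-slowing-down signature — while control records keep a constant
#' decay rate.
#'
#' Cohorts follow the clinical definitions: 1 = failed extubation,
#' re-intubated, survived; 2 = successful extubation (assigned a
#' pseudo-re-intubation time drawn from the cohort-1 duration distribution so
#' analyzed interval lengths match); 3 = not re-intubated, died; 4 =
#' re-intubated and died.
#'
#' Default cohort sizes (101 failures, 1475 controls) mirror the evaluable
#' heart-rate cohort sizes of the motivating study; baselines are
#' paediatric-plausible configuration defaults, not estimates.
#'
#' @param ... name-value overrides of any default listed below.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_cohort = c(101L, 1475L, 0L, 0L),  # cohorts 1-4
    variables = c("HR", "RR", "ABP"),
    dt = 5,
    baseline = c(HR = 120, RR = 30, ABP = 60),
    drift_amplitude = c(HR = 5, RR = 2, ABP = 3),
    drift_period_s = 7200,
    sigma = c(HR = 3, RR = 1.5, ABP = 2),
    lam_start = 0.5,
    lam_end = 0.005,
    ramp_shape = "linear",
    # duration of the extubated interval, seconds: lognormal, median 4 h,
    # truncated to [2 h, 24 h] so every record passes the 120-min rule
    duration_meanlog = log(4 * 3600),
    duration_sdlog = 0.6,
    duration_min = 7200,
    duration_max = 86400,
    # missing-data model: per-sample probability of starting a gap; run
    # lengths geometric, a mix of short (<= 10 step) and long (> 10 step)
    # gaps so both fill and splice branches of preprocessing are exercised
    gap_rate = 0.002,
    gap_short_mean = 3,
    gap_long_mean = 25,
    gap_long_prob = 0.1,
    ward_probs = c(PICU = 0.35, CICU = 0.50, NICU = 0.15),
    sex_probs = c(M = 0.52, F = 0.47, Unknown = 0.01),
    age_meanlog = log(1), age_sdlog = 1.2, age_max = 18
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("unknown cohort_config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (length(cfg$n_cohort) != 4L || any(cfg$n_cohort < 0)) {
    stop("'n_cohort' must give four non-negative cohort sizes")
  }
  check_ou_params(cfg$lam_start, max(cfg$sigma), cfg$dt)
  if (cfg$lam_end <= 0) stop("'lam_end' must be > 0")
  if (cfg$lam_end > cfg$lam_start) stop("'lam_end' must not exceed 'lam_start'")
  if (cfg$duration_min < 2 * cfg$dt) stop("durations must span >= 2 samples")
  if (cfg$gap_rate < 0 || cfg$gap_rate >= 1) stop("'gap_rate' must be in [0, 1)")
  invisible(cfg)
}

#' Draw a pseudo-re-intubation duration for a control record
#'
#' Successful extubations have no natural endpoint, so each control record is
#' assigned a pseudo-re-intubation time by resampling (with replacement) from
#' the empirical distribution of failure-record durations. Over many draws
#' the control duration distribution is then indistinguishable from the
#' failure one, which keeps analyzed interval lengths comparable across
#' cohorts.
#'
#' @param failure_durations non-empty numeric vector of failure durations
#'   (seconds).
#' @param n number of draws.
#' @return Numeric vector of `n` sampled durations.
#' @export
sample_pseudo_duration <- function(failure_durations, n = 1L) {
  if (!length(failure_durations)) {
    stop("'failure_durations' must be non-empty")
  }
  failure_durations[sample.int(length(failure_durations), n, replace = TRUE)]
}

#' Simulate the vital-sign series of one monitored record
#'
#' Realizes, per variable, baseline + slow sinusoidal drift + OU residual on
#' the 5-second grid, then injects runs of missing samples. For cohort-1
#' records (and cohort 4 when `ramp_cohort4 = TRUE`) the OU decay rate ramps
#' from `lam_start` down to `lam_end`, reaching its minimum exactly at the
#' record endpoint; cohorts 2 and 3 use a constant decay rate.
#'
#' @param record one-row data frame with at least `cohort` and `duration_s`.
#' @param config a [cohort_config()] list.
#' @param ramp_cohort4 should cohort-4 records also ramp? Default `TRUE`.
#' @return Named list (one element per variable) of numeric series with `NA`
#'   marking missing samples; each carries attributes `dt` and `variable`.
#' @export
simulate_record <- function(record, config = cohort_config(),
                            ramp_cohort4 = TRUE) {
  n <- as.integer(floor(record$duration_s / config$dt)) + 1L
  if (n < 2L) stop("record duration must span at least 2 samples")
  ramped <- record$cohort == 1L || (ramp_cohort4 && record$cohort == 4L)
  lam <- if (ramped) {
    ramp_schedule(n, config$lam_start, config$lam_end, config$ramp_shape)
  } else {
    config$lam_start
  }
  tt <- (seq_len(n) - 1L) * config$dt
  out <- vector("list", length(config$variables))
  names(out) <- config$variables
  for (v in config$variables) {
    resid <- simulate_ou(n, lam = lam, sigma = config$sigma[[v]],
                         dt = config$dt)
    phase <- stats::runif(1L, 0, 2 * pi)
    drift <- config$drift_amplitude[[v]] *
      sin(2 * pi * tt / config$drift_period_s + phase)
    x <- config$baseline[[v]] + drift + as.numeric(resid)
    x <- inject_gaps(x, config)
    attr(x, "dt") <- config$dt
    attr(x, "variable") <- v
    out[[v]] <- x
  }
  out
}

inject_gaps <- function(x, config) {
  if (config$gap_rate <= 0) return(x)
  n <- length(x)
  starts <- which(stats::runif(n) < config$gap_rate)
  for (s in starts) {
    long <- stats::runif(1L) < config$gap_long_prob
    mu <- if (long) config$gap_long_mean else config$gap_short_mean
    len <- 1L + stats::rgeom(1L, 1 / mu)
    x[s:min(n, s + len - 1L)] <- NA_real_
  }
  x
}

#' Generate a labelled synthetic cohort in memory
#'
#' Draws patient metadata (cohort, ward, age, sex), interval durations
#' (cohort-2 endpoints via [sample_pseudo_duration()]), and the per-variable
#' vital-sign series of every record. All randomness flows from `seed`, so a
#' given `config` + `seed` pair regenerates the identical dataset.
#'
#' @param config a [cohort_config()] list.
#' @param seed integer seed driving every random draw.
#' @return A list of class `"cohort_data"` with elements `records` (data
#'   frame of patient metadata: `patient_id`, `cohort`, `ward`, `age`, `sex`,
#'   `extubation_time`, `endpoint_time`, `duration_s`, `death_flag`),
#'   `series` (named list, per patient, of per-variable series), `config`,
#'   and `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  sizes <- as.integer(config$n_cohort)
  cohort <- rep.int(1:4, sizes)
  n <- length(cohort)
  if (n == 0L) stop("at least one cohort size must be positive")
  rtrunc_lnorm <- function(k) {
    d <- numeric(0)
    while (length(d) < k) {
      cand <- stats::rlnorm(k, config$duration_meanlog, config$duration_sdlog)
      d <- c(d, cand[cand >= config$duration_min & cand <= config$duration_max])
    }
    d[seq_len(k)]
  }
  duration <- numeric(n)
  fail_idx <- which(cohort %in% c(1L, 3L, 4L))
  duration[fail_idx] <- rtrunc_lnorm(length(fail_idx))
  ctrl_idx <- which(cohort == 2L)
  if (length(ctrl_idx)) {
    src <- duration[cohort == 1L]
    duration[ctrl_idx] <- if (length(src)) {
      sample_pseudo_duration(src, length(ctrl_idx))
    } else {
      rtrunc_lnorm(length(ctrl_idx))
    }
  }
  duration <- round(duration / config$dt) * config$dt
  age <- pmin(stats::rlnorm(n, config$age_meanlog, config$age_sdlog),
              config$age_max)
  records <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    cohort = cohort,
    ward = sample(names(config$ward_probs), n, replace = TRUE,
                  prob = config$ward_probs),
    age = age,
    sex = sample(names(config$sex_probs), n, replace = TRUE,
                 prob = config$sex_probs),
    extubation_time = 0,
    endpoint_time = duration,
    duration_s = duration,
    death_flag = cohort %in% c(3L, 4L),
    stringsAsFactors = FALSE
  )
  series <- vector("list", n)
  names(series) <- records$patient_id
  for (i in seq_len(n)) {
    series[[i]] <- simulate_record(records[i, ], config)
  }
  structure(list(records = records, series = series, config = config,
                 seed = seed),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("Synthetic extubation cohort dataset\n")
  cat("  records:", nrow(x$records), "\n")
  cat("  cohort sizes:",
      paste(sprintf("C%d=%d", 1:4, tabulate(x$records$cohort, 4L)),
            collapse = " "), "\n")
  cat("  variables:", paste(x$config$variables, collapse = ", "),
      " sampled every", x$config$dt, "s\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
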