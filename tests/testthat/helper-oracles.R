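# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the package implementations they check.

oracle_window_variance <- function(w) {
  m <- mean(w)
  sum((w - m)^2) / (length(w) - 1)
}

oracle_window_lag1 <- function(w) {
  m <- mean(w)
  n <- length(w)
  num <- 0
  for (i in seq_len(n - 1)) num <- num + (w[i] - m) * (w[i + 1] - m)
  den <- sum((w - m)^2)
  if (den == 0) NA_real_ else num / den
}

oracle_trace <- function(x, m, s) {
  starts <- seq(1, length(x) - m + 1, by = s)
  data.frame(
    variance = vapply(starts, function(a) oracle_window_variance(x[a:(a + m - 1)]),
                      numeric(1)),
    lag1_ac = vapply(starts, function(a) oracle_window_lag1(x[a:(a + m - 1)]),
                     numeric(1)))
}

oracle_kendall_S <- function(x) {
  S <- 0L
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  }
  S
}

# literal step-down execution of the Holm procedure
oracle_holm <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) reject[o[i]] <- TRUE else break
  }
  reject
}

# stationary AR(1) series with unit innovations
sim_ar1 <- function(n, phi) {
  as.numeric(stats::arima.sim(list(ar = phi), n))
}

# small helper: a quick stationary residual record for record-level tests
quick_record_series <- function(n_vars = 3, n = 1452, lam = 0.5, sigma = 1,
                                dt = 5) {
  vars <- c("HR", "RR", "ABP")[seq_len(n_vars)]
  out <- lapply(vars, function(v) simulate_ou(n, lam = lam, sigma = sigma,
                                              dt = dt))
  names(out) <- vars
  out
}
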