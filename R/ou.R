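#' Closed-form stationary moments of the linearized Ornstein-Uhlenbeck model
#'
#' Near a stable equilibrium the fluctuations of a monitored variable are
#' modelled as an Ornstein-Uhlenbeck (OU) process
#' \deqn{dx/dt = -\lambda x + \sigma \epsilon,}
#' where \eqn{x} is the perturbation from equilibrium, \eqn{\lambda > 0} the
#' magnitude of the dominant eigenvalue (a decay rate, 1/s), \eqn{\sigma} the
#' noise amplitude and \eqn{\epsilon} white noise. Its stationary variance is
#' \eqn{\sigma^2 / (2\lambda)} and its autocorrelation at lag \eqn{\tau} is
#' \eqn{e^{-\lambda\tau}}. As \eqn{\lambda \to 0} (the approach to a fold
#' bifurcation) the variance diverges and the autocorrelation tends to 1 —
#' the signature that critical slowing down detection relies on.
#'
#' @param lam decay rate \eqn{\lambda} in 1/seconds; must be strictly positive.
#' @param sigma noise amplitude (signal units per sqrt second); non-negative.
#' @param tau lag in seconds; non-negative.
#' @return A list with components `variance` (\eqn{\sigma^2/(2\lambda)}) and
#'   `acf` (\eqn{e^{-\lambda\tau}}).
#' @examples
#' ou_moments(lam = 0.5, sigma = 1, tau = 0)   # variance 1, acf 1
#' ou_moments(lam = 1, sigma = 1, tau = 1)     # variance 0.5, acf exp(-1)
#' @export
ou_moments <- function(lam, sigma, tau = 0) {
  check_ou_params(lam, sigma, dt = 1)
  if (any(tau < 0)) stop("'tau' must be non-negative")
  list(variance = sigma^2 / (2 * lam), acf = exp(-lam * tau))
}

check_ou_params <- function(lam, sigma, dt) {
  if (!is.numeric(lam) || any(!is.finite(lam)) || any(lam <= 0)) {
    stop("'lam' must be a finite, strictly positive decay rate (1/s)")
  }
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma < 0)) {
    stop("'sigma' must be finite and non-negative")
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("'dt' must be a single positive step in seconds")
  }
  invisible(TRUE)
}

#' Simulate a stationary Ornstein-Uhlenbeck residual series
#'
#' Generates an exact discretization of the OU process on a uniform grid:
#' \eqn{x_{k+1} = a x_k + e_k} with \eqn{a = e^{-\lambda \Delta t}} and
#' \eqn{e_k \sim N(0, \sigma^2 (1 - a^2) / (2\lambda))}. The exact update has
#' no step-size bias, which matters on the coarse 5-second monitor grid. The
#' initial state is drawn from the stationary law unless `x0` is supplied.
#'
#' `lam` may be a vector of length `n_steps` describing a time-varying decay
#' rate (e.g. a ramp toward zero ahead of a tipping point); the update then
#' uses the per-step \eqn{a_k} and innovation variance.
#'
#' @param n_steps number of samples to return (>= 2).
#' @param lam decay rate in 1/s; scalar, or vector of length `n_steps`.
#' @param sigma noise amplitude; `sigma = 0` gives deterministic decay.
#' @param dt sampling step in seconds (default 5, the monitor interval).
#' @param x0 optional fixed initial state; default draws from the stationary
#'   distribution of `lam[1]`.
#' @param seed optional integer seed; if supplied, the RNG state is set
#'   locally so the caller's stream is unaffected.
#' @return Numeric vector of length `n_steps` (residuals around baseline 0)
#'   with attribute `dt`.
#' @examples
#' x <- simulate_ou(2000, lam = 0.5, sigma = 1, seed = 1)
#' var(x)  # close to 1 = sigma^2 / (2 lam)
#' @export
simulate_ou <- function(n_steps, lam, sigma, dt = 5, x0 = NULL, seed = NULL) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 2) {
    stop("'n_steps' must be a single count >= 2")
  }
  n_steps <- as.integer(n_steps)
  check_ou_params(lam, sigma, dt)
  if (!length(lam) %in% c(1L, n_steps)) {
    stop("'lam' must be scalar or of length 'n_steps'")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  lam_vec <- rep_len(lam, n_steps)
  a <- exp(-lam_vec * dt)
  innov_sd <- sigma * sqrt((1 - a^2) / (2 * lam_vec))
  if (is.null(x0)) {
    x0 <- stats::rnorm(1L, 0, sigma / sqrt(2 * lam_vec[1L]))
  }
  if (length(lam) == 1L) {
    # constant decay rate: linear recursive filter, fast path
    e <- stats::rnorm(n_steps - 1L, 0, innov_sd[1L])
    x <- c(x0, stats::filter(e, a[1L], method = "recursive",
                             init = x0))
  } else {
    e <- stats::rnorm(n_steps - 1L, 0, innov_sd[-1L])
    x <- numeric(n_steps)
    x[1L] <- x0
    for (k in seq_len(n_steps - 1L)) {
      x[k + 1L] <- a[k + 1L] * x[k] + e[k]
    }
  }
  x <- as.numeric(x)
  attr(x, "dt") <- dt
  x
}

#' Decay-rate ramp schedule toward a fold bifurcation
#'
#' Builds the per-sample decay rate \eqn{\lambda_k} for a record: constant for
#' control records, or decreasing linearly in time from `lam_start` to
#' `lam_end` so that the smallest decay rate — the closest approach to the
#' bifurcation, where \eqn{\lambda \to 0} — is reached exactly at the end of
#' the record (the re-intubation or death time). `lam_end` must stay strictly
#' positive: at \eqn{\lambda = 0} the stationary variance is infinite.
#'
#' @param n_steps length of the record in samples.
#' @param lam_start decay rate at extubation time (1/s).
#' @param lam_end decay rate at the endpoint; `lam_end <= lam_start`.
#' @param shape `"linear"` (default) or `"constant"` (ignores `lam_end`).
#' @return Numeric vector of length `n_steps`.
#' @export
ramp_schedule <- function(n_steps, lam_start, lam_end = lam_start,
                          shape = c("linear", "constant")) {
  shape <- match.arg(shape)
  if (!is.finite(lam_start) || lam_start <= 0) stop("'lam_start' must be > 0")
  if (shape == "constant") return(rep(lam_start, n_steps))
  if (!is.finite(lam_end) || lam_end <= 0) {
    stop("'lam_end' must be > 0 (variance diverges at lam = 0)")
  }
  if (lam_end > lam_start) stop("'lam_end' must not exceed 'lam_start'")
  seq(lam_start, lam_end, length.out = n_steps)
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
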