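#' Unbiased variance of one indicator window
#'
#' The variance early-warning indicator of a window of n residual samples is
#' the unbiased sample variance \eqn{\sum_i (x_i - \bar x)^2 / (n - 1)}.
#'
#' @param window numeric vector of at least 2 samples.
#' @return Sample variance (signal units squared).
#' @export
window_variance <- function(window) {
  if (length(window) < 2L) stop("window must contain at least 2 samples")
  stats::var(as.numeric(window))
}

#' Lag-1 autocorrelation of one indicator window
#'
#' Computes
#' \deqn{r_1 = \frac{\sum_{i=1}^{n-1} (x_i - \bar x)(x_{i+1} - \bar x)}
#'                  {\sum_{i=1}^{n} (x_i - \bar x)^2}}
#' with \eqn{\bar x} the window mean. Under critical slowing down the
#' residuals decorrelate more slowly, so \eqn{r_1} rises toward 1. A constant
#' window has a zero denominator; `NA` is returned and the window is skipped
#' in the trace.
#'
#' @param window numeric vector of at least 3 samples.
#' @return Lag-1 autocorrelation in \[-1, 1\], or `NA` for a constant window.
#' @export
window_lag1_autocorr <- function(window) {
  if (length(window) < 3L) stop("window must contain at least 3 samples")
  x <- as.numeric(window)
  xc <- x - mean(x)
  den <- sum(xc^2)
  if (den == 0) return(NA_real_)
  n <- length(x)
  sum(xc[-n] * xc[-1L]) / den
}

#' Sliding-window early-warning-signal trace
#'
#' Slides a window of `window_len` minutes along the residual series in steps
#' of `step` minutes and records, per window, the variance and the lag-1
#' autocorrelation. Windows are left-aligned and half-open in sample index
#' (`m = window_len * 60 / dt` samples starting at t), and the trace is
#' timestamped by window start. The resulting pair of secondary time series
#' is what the trend tests operate on: under critical slowing down both rise
#' as the record approaches its endpoint.
#'
#' Implemented with cumulative sums (the series is centred on its global mean
#' first for numerical stability), so the cost is linear in series length.
#'
#' @param x gap-free residual series on a uniform grid.
#' @param window_len window length in minutes (default 60; 30 and 15 are the
#'   usual sensitivity settings).
#' @param step slide step in minutes (default 1).
#' @param dt sampling interval in seconds (default from `attr(x, "dt")`,
#'   else 5).
#' @return A data frame of class `"ews_trace"` with columns `t_start_s`,
#'   `variance`, `lag1_ac` (`NA` for skipped constant windows), and
#'   attributes `window_len`, `step`, `dt`, `variable`.
#' @examples
#' x <- simulate_ou(1452, lam = 0.5, sigma = 1, seed = 1)
#' tr <- compute_ews_trace(x)
#' nrow(tr)  # 62 one-minute steps in a 121-minute record
#' @export
compute_ews_trace <- function(x, window_len = 60, step = 1, dt = NULL) {
  if (is.null(dt)) dt <- attr(x, "dt")
  if (is.null(dt)) dt <- 5
  m <- window_len * 60 / dt
  s <- step * 60 / dt
  if (abs(m - round(m)) > 1e-8 || m < 2) {
    stop("'window_len' must span an integer number (>= 2) of samples")
  }
  if (abs(s - round(s)) > 1e-8 || s < 1) {
    stop("'step' must span a positive integer number of samples")
  }
  m <- as.integer(round(m)); s <- as.integer(round(s))
  if (anyNA(x)) stop("series must be gap-free (run preprocessing first)")
  n <- length(x)
  if (n < m) stop("series shorter than one window")
  starts <- seq.int(1L, n - m + 1L, by = s)
  ends <- starts + m - 1L
  xc <- as.numeric(x) - mean(x)
  c1 <- c(0, cumsum(xc))
  c2 <- c(0, cumsum(xc^2))
  cp <- c(0, cumsum(xc[-n] * xc[-1L]))
  s1 <- c1[ends + 1L] - c1[starts]
  s2 <- c2[ends + 1L] - c2[starts]
  sp <- cp[ends] - cp[starts]
  wmean <- s1 / m
  css <- s2 - s1^2 / m               # within-window sum of squares
  css <- pmax(css, 0)
  variance <- css / (m - 1L)
  num <- sp - wmean * (2 * s1 - xc[starts] - xc[ends]) + (m - 1L) * wmean^2
  lag1 <- ifelse(css > 0, num / css, NA_real_)
  out <- data.frame(t_start_s = (starts - 1L) * dt,
                    variance = variance,
                    lag1_ac = lag1)
  attr(out, "window_len") <- window_len
  attr(out, "step") <- step
  attr(out, "dt") <- dt
  attr(out, "variable") <- attr(x, "variable")
  class(out) <- c("ews_trace", "data.frame")
  out
}

#' @export
plot.ews_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  tmin <- x$t_start_s / 60
  graphics::plot(tmin, x$variance, type = "l", xlab = "window start (min)",
                 ylab = "variance",
                 main = attr(x, "variable") %||% "EWS trace", ...)
  graphics::plot(tmin, x$lag1_ac, type = "l", xlab = "window start (min)",
                 ylab = "lag-1 autocorrelation", ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
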