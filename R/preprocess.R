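#' Fill short gaps and splice out long ones
#'
#' Monitor dropouts appear as runs of missing samples. Runs of at most
#' `max_fill_gap` steps are filled: every missing sample in the run is
#' replaced by the mean of the two flanking observed values. Longer runs are
#' deleted and the flanks concatenated, so the record shortens by the run
#' length; downstream windows treat the spliced series as contiguous.
#' Leading and trailing missing runs have only one flank and are deleted.
#'
#' @param x numeric series on a uniform grid, `NA` marking missing samples.
#' @param max_fill_gap longest run (in steps) that is filled rather than
#'   spliced out (default 10).
#' @return Gap-free numeric vector with attributes `n_filled` (samples
#'   filled), `n_spliced` (samples removed), and `splice_points` (indices in
#'   the output after which a splice occurred).
#' @examples
#' handle_gaps(c(1, NA, 3))  # 1 2 3
#' @export
handle_gaps <- function(x, max_fill_gap = 10L) {
  dt_attr <- attr(x, "dt")
  var_attr <- attr(x, "variable")
  x <- as.numeric(x)
  if (all(is.na(x))) stop("series is entirely missing")
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- rep(TRUE, length(x))
  n_filled <- 0L
  splice_after <- integer(0)  # input index of last kept sample before splice
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    s <- starts[k]; e <- ends[k]; len <- r$lengths[k]
    if (s == 1L || e == length(x) || len > max_fill_gap) {
      keep[s:e] <- FALSE
      if (s > 1L && e < length(x)) splice_after <- c(splice_after, s - 1L)
    } else {
      x[s:e] <- (x[s - 1L] + x[e + 1L]) / 2
      n_filled <- n_filled + len
    }
  }
  out <- x[keep]
  # map splice positions from input to output indexing
  splice_points <- vapply(splice_after, function(i) sum(keep[seq_len(i)]),
                          integer(1))
  attr(out, "n_filled") <- n_filled
  attr(out, "n_spliced") <- sum(!keep)
  attr(out, "splice_points") <- splice_points
  attr(out, "dt") <- dt_attr
  attr(out, "variable") <- var_attr
  out
}

#' Remove the long-term trend with a Gaussian filter
#'
#' Smooths the series with a Gaussian kernel (standard deviation `kernel_sd`
#' seconds, truncated at four standard deviations, reflective boundary) and
#' subtracts the smoothed curve, leaving the residual fluctuations that the
#' early-warning indicators are computed on. Detrending removes slow baseline
#' wander that would otherwise inflate windowed variance and autocorrelation
#' and produce false trend positives.
#'
#' The default bandwidth of 10 minutes sits well below the 60-minute analysis
#' window, so only variation that is long-term relative to the indicator
#' windows is removed.
#'
#' @param x gap-free numeric series.
#' @param kernel_sd kernel standard deviation in seconds (> 0; default 600).
#' @param dt sampling step in seconds; taken from `attr(x, "dt")` if present.
#' @return Residual series (input minus smooth) carrying a `trend` attribute
#'   with the smoothed curve, plus any attributes of the input.
#' @export
detrend_gaussian <- function(x, kernel_sd = 600, dt = NULL) {
  if (is.null(dt)) dt <- attr(x, "dt")
  if (is.null(dt)) dt <- 5
  if (!is.numeric(kernel_sd) || kernel_sd <= 0) {
    stop("'kernel_sd' must be a positive bandwidth in seconds")
  }
  if (anyNA(x)) stop("series must be gap-free (run handle_gaps first)")
  n <- length(x)
  if (n < 2L) stop("series too short to detrend")
  h <- min(as.integer(ceiling(4 * kernel_sd / dt)), n - 1L)
  k <- stats::dnorm(seq(-h, h) * dt, sd = kernel_sd)
  k <- k / sum(k)
  xv <- as.numeric(x)
  padded <- c(xv[(h + 1L):2L], xv, xv[(n - 1L):(n - h)])
  sm <- stats::convolve(padded, rev(k), type = "open")
  trend <- sm[(2L * h + 1L):(2L * h + n)]
  res <- xv - trend
  attributes(res) <- attributes(x)
  attr(res, "trend") <- trend
  res
}

#' Replace residual outliers by the residual mean
#'
#' Computes the mean \eqn{\mu} and standard deviation \eqn{\sigma} of the
#' residual series once, then replaces every value outside
#' \eqn{[\mu - 3\sigma, \mu + 3\sigma]} with \eqn{\mu}. The moments are not
#' re-estimated after replacement. With \eqn{\sigma = 0} no value can fall
#' outside the band and the series is returned unchanged.
#'
#' @param x non-empty gap-free residual series.
#' @return Series with outliers replaced; attribute `n_clipped` counts the
#'   replacements.
#' @export
clip_outliers <- function(x) {
  if (!length(x)) stop("empty series")
  if (anyNA(x)) stop("series must be gap-free")
  mu <- mean(x)
  s <- stats::sd(as.numeric(x))
  out <- as.numeric(x)
  bad <- if (is.na(s) || s == 0) logical(length(out)) else abs(out - mu) > 3 * s
  out[bad] <- mu
  attributes(out) <- attributes(x)
  attr(out, "n_clipped") <- sum(bad)
  out
}

#' Full preprocessing of one raw series
#'
#' Chains the preprocessing stages in order: gap handling (fill short runs,
#' splice long ones), Gaussian detrending, and outlier replacement. A single
#' detrending pass is applied, after gap handling and before clipping; the
#' returned residual series is what the indicator windows consume.
#'
#' @inheritParams handle_gaps
#' @inheritParams detrend_gaussian
#' @return Residual series with provenance attributes (`n_filled`,
#'   `n_spliced`, `splice_points`, `n_clipped`).
#' @export
preprocess_series <- function(x, max_fill_gap = 10L, kernel_sd = 600,
                              dt = NULL) {
  g <- handle_gaps(x, max_fill_gap = max_fill_gap)
  r <- detrend_gaussian(g, kernel_sd = kernel_sd, dt = dt)
  out <- clip_outliers(r)
  attr(out, "trend") <- NULL
  out
}

#' Filter records by analyzable interval duration
#'
#' Indicator windows are 60 minutes long, so a record whose extubated
#' interval is shorter than twice the window cannot support a meaningful
#' trend estimate. Records with `endpoint_time - extubation_time` strictly
#' less than `min_duration` are excluded; exactly `min_duration` is retained.
#'
#' @param records data frame with `extubation_time` and `endpoint_time`
#'   (seconds).
#' @param min_duration minimum analyzable duration in seconds (default 7200,
#'   i.e. 120 minutes).
#' @return List with `retained` (subset of `records`) and `excluded` (data
#'   frame of dropped records with a `reason` column).
#' @export
eligibility_filter <- function(records, min_duration = 7200) {
  if (!nrow(records)) {
    return(list(retained = records,
                excluded = cbind(records, reason = character(0))))
  }
  dur <- records$endpoint_time - records$extubation_time
  short <- dur < min_duration
  excluded <- records[short, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- sprintf("duration %.0f s < %.0f s", dur[short],
                               min_duration)
  } else {
    excluded$reason <- character(0)
  }
  list(retained = records[!short, , drop = FALSE], excluded = excluded)
}
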