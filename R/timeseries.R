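#' Uniformly sampled time series
#'
#' Lightweight container for a uniformly sampled signal with physical units
#' and a per-sample validity mask.  Valid samples form unions of contiguous
#' runs; invalid samples (e.g. ramp regions, slack-spring intervals) are
#' skipped by downstream spectral analysis rather than zero-filled.
#'
#' @param values Numeric vector of samples.
#' @param rate Sampling rate in samples per second (> 0).
#' @param start Time of the first sample in seconds.
#' @param units Free-text unit label (e.g. `"deg"`, `"cm/s"`).
#' @param valid Logical vector of the same length as `values`, or `NULL`
#'   for all-valid.
#' @return An object of class `"phirf_ts"`.
#' @export
time_series <- function(values, rate, start = 0, units = "", valid = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a positive scalar (samples/second)")
  values <- as.numeric(values)
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  if (length(valid) != length(values))
    stop("`values` and `valid` must have equal length")
  structure(
    list(values = values, rate = rate, start = start,
         units = units, valid = as.logical(valid)),
    class = "phirf_ts")
}

#' Sample times of a time series
#' @param x A `"phirf_ts"` object.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_times <- function(x) {
  x$start + (seq_along(x$values) - 1) / x$rate
}

#' @export
print.phirf_ts <- function(x, ...) {
  dur <- length(x$values) / x$rate
  cat(sprintf("<time series> %d samples @ %g Hz (%.1f s), units '%s', %d%% valid\n",
              length(x$values), x$rate, dur, x$units,
              round(100 * mean(x$valid))))
  invisible(x)
}

#' @export
length.phirf_ts <- function(x) length(x$values)

#' Root mean square over valid samples
#'
#' @param x A `"phirf_ts"` object or numeric vector.
#' @return Scalar RMS value.
#' @export
rms <- function(x) {
  if (inherits(x, "phirf_ts")) {
    v <- x$values[x$valid]
  } else {
    v <- as.numeric(x)
  }
  v <- v[is.finite(v)]
  if (length(v) < 1L) stop("rms(): no valid samples")
  sqrt(mean(v^2))
}

#' Numerical differentiation of a time series
#'
#' Central differences in the interior with one-sided differences at the
#' signal endpoints and at the boundaries of invalid gaps, so that no
#' derivative estimate straddles an invalid sample.
#'
#' @param x A `"phirf_ts"` object with at least 3 samples.
#' @return A `"phirf_ts"` with units gaining "/s".
#' @export
differentiate <- function(x) {
  stopifnot(inherits(x, "phirf_ts"))
  n <- length(x$values)
  if (n < 3L) stop("differentiate(): need at least 3 samples")
  v <- x$values
  r <- x$rate
  d <- rep(NA_real_, n)
  runs <- valid_runs(x$valid)
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1L]; b <- runs[i, 2L]
    m <- b - a + 1L
    if (m == 1L) next
    seg <- v[a:b]
    ds <- numeric(m)
    ds[1L] <- (seg[2L] - seg[1L]) * r
    ds[m] <- (seg[m] - seg[m - 1L]) * r
    if (m > 2L) ds[2:(m - 1L)] <- (seg[3:m] - seg[1:(m - 2L)]) * r / 2
    d[a:b] <- ds
  }
  valid <- x$valid & !is.na(d)
  d[is.na(d)] <- 0
  time_series(d, r, x$start, units = paste_units_per_s(x$units), valid = valid)
}

paste_units_per_s <- function(u) {
  if (identical(u, "")) "1/s" else paste0(u, "/s")
}

# start/end indices (inclusive) of contiguous valid runs
valid_runs <- function(valid) {
  n <- length(valid)
  if (n == 0L || !any(valid)) return(matrix(integer(0), ncol = 2L))
  d <- diff(c(FALSE, valid, FALSE))
  cbind(which(d == 1L), which(d == -1L) - 1L)
}

#' Correct a fixed acquisition group delay
#'
#' Advances the signal in time by `delay` seconds by shifting samples to the
#' nearest integer number of samples; the trailing region that no longer has
#' data is marked invalid.  The sub-sample residual of the shift is attached
#' as attribute `"subsample_residual"` (in samples).
#'
#' @param x A `"phirf_ts"` object.
#' @param delay Non-negative delay in seconds (e.g. 0.048 for a 48-ms
#'   hardware group delay).
#' @return A `"phirf_ts"` object of the same length.
#' @export
correct_group_delay <- function(x, delay) {
  stopifnot(inherits(x, "phirf_ts"))
  if (!is.numeric(delay) || length(delay) != 1L || delay < 0)
    stop("`delay` must be a non-negative scalar in seconds")
  n <- length(x$values)
  shift_exact <- delay * x$rate
  m <- as.integer(round(shift_exact))
  if (m >= n) stop("`delay` exceeds the signal duration")
  residual <- shift_exact - m
  if (m == 0L) {
    out <- x
  } else {
    v <- c(x$values[(m + 1L):n], rep(x$values[n], m))
    valid <- c(x$valid[(m + 1L):n], rep(FALSE, m))
    out <- time_series(v, x$rate, x$start, x$units, valid)
  }
  attr(out, "subsample_residual") <- residual
  out
}

#' Cumulative time integral of a time series
#'
#' Trapezoidal cumulative integration from the first sample (zero initial
#' condition); used e.g. to recover position from velocity signals.
#'
#' @param x A `"phirf_ts"` object.
#' @return A `"phirf_ts"` whose units lose a "/s".
#' @export
integrate_ts <- function(x) {
  stopifnot(inherits(x, "phirf_ts"))
  v <- x$values
  n <- length(v)
  h <- 1 / x$rate
  ci <- c(0, cumsum((v[-1] + v[-n]) / 2 * h))
  u <- sub("/s$", "", x$units)
  if (identical(u, x$units)) u <- paste0(x$units, "*s")
  time_series(ci, x$rate, x$start, u, x$valid)
}
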