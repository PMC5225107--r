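#' Mean stride time and fundamental frequency from cycle events
#'
#' @param events Strictly increasing vector of cycle-event times (seconds),
#'   e.g. heel strikes of a reference leg; at least 3 events.
#' @return List with `T_bar` (mean stride time, s) and `f0` (= 1/T_bar, Hz).
#' @export
stride_stats <- function(events) {
  events <- as.numeric(events)
  if (length(events) < 3L) stop("stride_stats(): need at least 3 events")
  if (any(diff(events) <= 0)) stop("stride_stats(): event times must be strictly increasing")
  T_bar <- mean(diff(events))
  list(T_bar = T_bar, f0 = 1 / T_bar)
}

# discontinuous phase: theta_d(t) = (k-1) + f0 (t - t_k) on [t_k, t_{k+1});
# extrapolated with slope f0 before the first and after the last event
theta_discontinuous <- function(events, t, f0) {
  k <- findInterval(t, events)       # 0 before first event
  k0 <- pmax(k, 1L)
  (k0 - 1L) + f0 * (t - events[k0])
}

#' Causal continuously-differentiable phase estimate
#'
#' Builds the discontinuous event-based phase
#' `theta_d(t) = k + f0 (t - t_k)` and smooths it with the critically damped
#' causal second-order filter
#' `theta'' + 2 d (theta' - f0) + d^2 theta = d^2 theta_d(t)`,
#' whose unit-slope feedforward term makes it track strictly periodic gait
#' exactly.  The filter state `[theta, theta']` is advanced with an exact
#' first-order-hold discretization (closed form for the double pole at -d),
#' which is exact for the piecewise-linear `theta_d` between events.  The
#' estimate at time t depends only on events and samples up to t.
#'
#' @param events Strictly increasing cycle-event times (seconds).
#' @param tgrid Uniform sample times (seconds) on which to evaluate the phase.
#' @param d Filter rate constant in 1/s (default 2).
#' @param stats Optional result of [stride_stats()]; computed if `NULL`.
#' @return An object of class `"phase_map"`: list with `tgrid`, `theta`
#'   (cycles), `theta_dot` (cycles/s), `T_bar`, `f0`, `d`.
#' @export
approximate_phase <- function(events, tgrid, d = 2, stats = NULL) {
  if (is.null(stats)) stats <- stride_stats(events)
  f0 <- stats$f0
  if (d <= 0) stop("`d` must be > 0")
  tgrid <- as.numeric(tgrid)
  n <- length(tgrid)
  if (n < 2L) stop("`tgrid` must have at least 2 samples")
  h <- diff(tgrid)
  if (max(abs(h - h[1])) > 1e-9 * h[1]) stop("`tgrid` must be uniform")
  h <- h[1]

  thd <- theta_discontinuous(events, tgrid, f0)
  w <- d^2 * thd + 2 * d * f0          # filter drive

  # exact matrices for A = [[0,1],[-d^2,-2d]] (double eigenvalue -d), B=[0,1]
  ed <- exp(-d * h)
  Ad <- ed * matrix(c(1 + d * h, -d^2 * h, h, 1 - d * h), 2, 2)
  I0 <- (1 - ed) / d
  I1 <- (1 - (1 + d * h) * ed) / d^2
  I2 <- (2 - ed * (d^2 * h^2 + 2 * d * h + 2)) / d^3
  G0 <- c(I1, I0 - d * I1)                      # int_0^h e^{As} B ds
  J  <- c(I2, I1 - d * I2)                      # int_0^h e^{As} B s ds
  G1 <- G0 - J / h                              # ramp-input weight

  theta <- numeric(n)
  theta_dot <- numeric(n)
  x1 <- thd[1]; x2 <- f0                        # theta(0)=theta_d(0), theta'(0)=f0
  theta[1] <- x1; theta_dot[1] <- x2
  a11 <- Ad[1, 1]; a12 <- Ad[1, 2]; a21 <- Ad[2, 1]; a22 <- Ad[2, 2]
  for (k in seq_len(n - 1L)) {
    wk <- w[k]; dw <- w[k + 1L] - wk
    y1 <- a11 * x1 + a12 * x2 + G0[1] * wk + G1[1] * dw
    y2 <- a21 * x1 + a22 * x2 + G0[2] * wk + G1[2] * dw
    x1 <- y1; x2 <- y2
    theta[k + 1L] <- x1
    theta_dot[k + 1L] <- x2
  }
  if (any(theta_dot <= 0)) {
    i <- which(theta_dot <= 0)[1]
    stop(sprintf("approximate_phase(): theta_dot <= 0 at t = %.3f s; phase is not invertible there",
                 tgrid[i]))
  }
  structure(list(tgrid = tgrid, theta = theta, theta_dot = theta_dot,
                 T_bar = stats$T_bar, f0 = f0, d = d),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase map> %d samples, theta in [%.2f, %.2f] cycles, T_bar = %.3f s, d = %g /s\n",
              length(x$theta), x$theta[1], x$theta[length(x$theta)], x$T_bar, x$d))
  invisible(x)
}

#' Resample signals from time to phase
#'
#' Inverts the phase map by monotone (Fritsch-Carlson) cubic interpolation of
#' `(theta, t)` to obtain `p(phase)`, then samples every channel and the
#' phase rate `q(phase) = theta_dot(p(phase))` on a uniform phase grid with
#' spacing `dphi`, starting at the first integer phase covered.  Samples that
#' map into invalid time intervals are marked invalid.
#'
#' @param pm A `"phase_map"`.
#' @param channels Named list of `"phirf_ts"` objects sharing the phase-map
#'   time base.
#' @param dphi Phase grid spacing in cycles; `1/dphi` must be an integer
#'   (default 1/128).
#' @return An object of class `"phase_domain"`: list with `grid` (cycles),
#'   `dphi`, `channels` (named list of value vectors), `q` (cycles/s),
#'   `valid`, `units`, `T_bar`, `f0`.
#' @export
to_phase_domain <- function(pm, channels, dphi = 1 / 128) {
  stopifnot(inherits(pm, "phase_map"))
  spc <- 1 / dphi
  if (abs(spc - round(spc)) > 1e-9) stop("`1/dphi` must be an integer")
  if (any(diff(pm$theta) <= 0)) stop("phase map must be strictly increasing")
  lo <- ceiling(pm$theta[1] - 1e-12)
  hi <- floor(pm$theta[length(pm$theta)] + 1e-12)
  if (hi - lo < 1) stop("phase map covers less than one full cycle")
  grid <- lo + seq(0, (hi - lo) * round(spc)) * dphi
  p <- stats::splinefun(pm$theta, pm$tgrid, method = "monoH.FC")(grid)
  qf <- stats::splinefun(pm$tgrid, pm$theta_dot, method = "monoH.FC")
  q <- qf(p)

  vals <- list()
  units <- character(0)
  valid <- rep(TRUE, length(grid))
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    stopifnot(inherits(ch, "phirf_ts"))
    tt <- ts_times(ch)
    f <- stats::splinefun(tt, ch$values, method = "monoH.FC")
    vals[[nm]] <- f(p)
    # a phase sample is valid if it falls strictly inside a valid time run
    vmask <- stats::approx(tt, as.numeric(ch$valid), xout = p,
                           method = "constant", rule = 2, f = 0)$y > 0.5 &
             stats::approx(tt, as.numeric(ch$valid), xout = p,
                           method = "constant", rule = 2, f = 1)$y > 0.5
    valid <- valid & vmask & p >= tt[1] & p <= tt[length(tt)]
    units[nm] <- ch$units
  }
  structure(list(grid = grid, dphi = dphi, channels = vals, q = q,
                 valid = valid, units = units,
                 T_bar = pm$T_bar, f0 = pm$f0),
            class = "phase_domain")
}

#' @export
print.phase_domain <- function(x, ...) {
  cat(sprintf("<phase-domain signals> %d samples (%.0f cycles at 1/%d cycle), channels: %s\n",
              length(x$grid), diff(range(x$grid)), round(1 / x$dphi),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# least-squares harmonic fit of order M; returns coefficients a0, ac[m], as[m]
fit_harmonics <- function(phase, values, M) {
  X <- matrix(1, length(phase), 1 + 2 * M)
  for (m in seq_len(M)) {
    X[, 2 * m] <- cos(2 * pi * m * phase)
    X[, 2 * m + 1] <- sin(2 * pi * m * phase)
  }
  cf <- stats::.lm.fit(X, values)$coefficients
  list(a0 = cf[1], ac = cf[2 * seq_len(M)], as = cf[2 * seq_len(M) + 1])
}

eval_harmonics_coef <- function(cf, phase, deriv = 0L) {
  M <- length(cf$ac)
  out <- if (deriv == 0L) rep(cf$a0, length(phase)) else numeric(length(phase))
  for (m in seq_len(M)) {
    w <- 2 * pi * m
    if (deriv == 0L) {
      out <- out + cf$ac[m] * cos(w * phase) + cf$as[m] * sin(w * phase)
    } else {
      out <- out + w * (-cf$ac[m] * sin(w * phase) + cf$as[m] * cos(w * phase))
    }
  }
  out
}

#' Phase-locked cycle mean and deviations
#'
#' Estimates the cycle mean of every channel by a least-squares harmonic fit
#' of order `M` over valid samples (an exact, analytically differentiable
#' representation of the phase-locked waveform), and returns the deviations
#' of each channel from its cycle mean.  The phase-rate deviation uses the
#' scalar `f0`, not a fitted mean.
#'
#' @param pds A `"phase_domain"` object.
#' @param M Harmonic order (default 20).
#' @param channels Channels to average; defaults to all.
#' @return List with `mean` (class `"cycle_mean"`: harmonic coefficients per
#'   channel plus `f0`, `M`) and `dev` (a `"phase_domain"` whose channels are
#'   deviations and whose `q` is `q - f0`).
#' @export
cycle_mean <- function(pds, M = 20, channels = names(pds$channels)) {
  stopifnot(inherits(pds, "phase_domain"))
  n_cycles <- diff(range(pds$grid))
  if (n_cycles < 2) stop("cycle_mean(): need at least 2 complete cycles")
  if (n_cycles < 10) warning("cycle_mean(): fewer than 10 cycles; cycle mean will be noisy")
  ok <- pds$valid
  coefs <- list()
  dev <- pds
  for (nm in channels) {
    cf <- fit_harmonics(pds$grid[ok], pds$channels[[nm]][ok], M)
    coefs[[nm]] <- cf
    dev$channels[[nm]] <- pds$channels[[nm]] - eval_harmonics_coef(cf, pds$grid)
  }
  dev$q <- pds$q - pds$f0
  cm <- structure(list(coef = coefs, f0 = pds$f0, T_bar = pds$T_bar, M = M,
                       n_cycles = n_cycles, units = pds$units[channels]),
                  class = "cycle_mean")
  list(mean = cm, dev = dev)
}

#' Evaluate a cycle mean (or its derivative) at given phases
#'
#' @param object A `"cycle_mean"`.
#' @param phase Phases in cycles at which to evaluate.
#' @param channel Channel name (defaults to the first fitted channel).
#' @param deriv 0 for the waveform, 1 for its exact derivative per cycle.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.cycle_mean <- function(object, phase, channel = names(object$coef)[1],
                               deriv = 0L, ...) {
  eval_harmonics_coef(object$coef[[channel]], phase, deriv = deriv)
}

#' @export
print.cycle_mean <- function(x, ...) {
  cat(sprintf("<cycle mean> order-%d harmonic fit over %.0f cycles; channels: %s\n",
              x$M, x$n_cycles, paste(names(x$coef), collapse = ", ")))
  invisible(x)
}

# weighted average of cycle-mean harmonic coefficients across trials
pool_cycle_means <- function(cms, weights = NULL) {
  if (is.null(weights)) weights <- vapply(cms, function(x) x$n_cycles, numeric(1))
  weights <- weights / sum(weights)
  out <- cms[[1]]
  for (nm in names(out$coef)) {
    a0 <- sum(vapply(seq_along(cms), function(i) cms[[i]]$coef[[nm]]$a0 * weights[i], numeric(1)))
    ac <- Reduce(`+`, lapply(seq_along(cms), function(i) cms[[i]]$coef[[nm]]$ac * weights[i]))
    as <- Reduce(`+`, lapply(seq_along(cms), function(i) cms[[i]]$coef[[nm]]$as * weights[i]))
    out$coef[[nm]] <- list(a0 = a0, ac = ac, as = as)
  }
  out$f0 <- sum(vapply(seq_along(cms), function(i) cms[[i]]$f0 * weights[i], numeric(1)))
  out$T_bar <- sum(vapply(seq_along(cms), function(i) cms[[i]]$T_bar * weights[i], numeric(1)))
  out$n_cycles <- sum(vapply(cms, function(x) x$n_cycles, numeric(1)))
  out
}
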