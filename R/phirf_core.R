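#' Transient impulse response from an HTF estimate
#'
#' Converts the harmonic transfer function of one output channel to its
#' phase-domain impulse response by a two-dimensional inverse Fourier
#' transform: for each mode k, `g_k(tau)` is the inverse transform of the
#' band-tapered `H_k(f1)` over input frequency (negative frequencies filled
#' by the conjugate-symmetry relation `H_{-k}(-f1) = Conj(H_k(f1))`), and
#' `h(phase_r, phase_s) = Re sum_k g_k(phase_r - phase_s) exp(i 2 pi k phase_r)`.
#' A Hann edge taper over the top fraction of the band and a linear taper
#' over the highest modes suppress Gibbs ringing from the finite band.
#'
#' @param htf An `"htf_estimate"`.
#' @param channel Output channel name (default first).
#' @param phases Stimulus-phase grid in `[0,1)` (default 50 equispaced).
#' @param tau_range Lag range in cycles (default `c(-1, 4)`; the negative
#'   part retains the acausal region as a noise diagnostic).
#' @param dtau Lag grid step in cycles (default the HTF's phase spacing).
#' @param taper_frac Fraction of the band tapered at the top edge (default 0.2).
#' @param mode_taper Number of top modes tapered linearly to zero (default 2).
#' @return An object of class `"transient_irf"`: matrix `h` `[lag, phase]`
#'   with grids `tau`, `phases`.
#' @export
htf_to_irf <- function(htf, channel = htf$outputs[1], phases = (0:49) / 50,
                       tau_range = c(-1, 4), dtau = htf$dphi,
                       taper_frac = 0.2, mode_taper = 2) {
  stopifnot(inherits(htf, "htf_estimate"))
  if (!channel %in% htf$outputs) stop("channel not in HTF estimate: ", channel)
  modes <- htf$modes
  if (!setequal(modes, -modes))
    stop("htf_to_irf(): mode set is not conjugate-complete")
  H <- htf$H[, , channel, drop = TRUE]      # [freq, mode]
  f <- htf$f1
  K <- htf$k_max

  # band taper on f1 (top taper_frac of (0, f_max]) and mode taper
  wf <- rep(1, length(f))
  edge <- htf$f_max * (1 - taper_frac)
  hi <- f > edge
  wf[hi] <- 0.5 + 0.5 * cos(pi * (f[hi] - edge) / (htf$f_max - edge))
  wk <- rep(1, length(modes))
  if (mode_taper > 0) {
    for (j in seq_len(mode_taper)) {
      wk[abs(modes) == K - j + 1] <- j / (mode_taper + 1)
    }
  }
  Ht <- H * wf
  Ht[!is.finite(Re(Ht))] <- 0

  tau <- seq(tau_range[1], tau_range[2], by = dtau)
  # g_k(tau) = df * sum_{f>=0} H_k(f) e^{i2pi f tau}
  #          + df * sum_{f>0} Conj(H_{-k}(f)) e^{-i2pi f tau}
  Epos <- exp(2i * pi * outer(tau, f))               # [tau, freq]
  Eneg <- Conj(Epos[, f > 0, drop = FALSE])
  g <- matrix(0 + 0i, length(tau), length(modes))
  for (ki in seq_along(modes)) {
    mi <- as.character(modes[ki])
    mni <- as.character(-modes[ki])
    g[, ki] <- htf$df * wk[ki] *
      (Epos %*% Ht[, mi] + Eneg %*% Conj(Ht[f > 0, mni]))
  }
  # h(phase_s + tau, phase_s): fold the response-phase harmonic factor
  P <- g * exp(2i * pi * outer(tau, modes))          # [tau, mode]
  Emat <- exp(2i * pi * outer(modes, phases))        # [mode, phase]
  h <- Re(P %*% Emat)
  structure(list(h = h, tau = tau, phases = phases, dtau = dtau,
                 channel = channel, input = htf$input,
                 units = htf$units, T_bar = htf$T_bar, f0 = htf$f0),
            class = "transient_irf")
}

# cumulative trapezoid of columns from the tau = 0 row, signed both ways
cumtrapz_from_zero <- function(h, tau) {
  i0 <- which.min(abs(tau))
  if (abs(tau[i0]) > 1e-9) stop("lag grid must contain tau = 0")
  dt <- diff(tau)
  out <- h * 0
  n <- length(tau)
  if (i0 < n) {
    seg <- (h[i0:(n - 1L), , drop = FALSE] + h[(i0 + 1L):n, , drop = FALSE]) / 2 *
      dt[i0:(n - 1L)]
    out[(i0 + 1L):n, ] <- apply(seg, 2, cumsum)
  }
  if (i0 > 1L) {
    seg <- (h[1:(i0 - 1L), , drop = FALSE] + h[2:i0, , drop = FALSE]) / 2 * dt[1:(i0 - 1L)]
    out[(i0 - 1L):1, ] <- -apply(seg[rev(seq_len(i0 - 1L)), , drop = FALSE], 2, cumsum)
  }
  out
}

#' Phase impulse response by integrating the phase-derivative response
#'
#' Integrates the phase-derivative impulse response over response phase,
#' accumulating forward from stimulus onset so that
#' `h_theta(phase_s, phase_s) = 0`; a transient phase-rate response thus
#' integrates to the permanent phase shift it causes.
#'
#' @param hq A `"transient_irf"` for the phase-rate channel.
#' @param flip_sign If `TRUE`, integrate with the opposite orientation
#'   (response-to-onset); exposed for sensitivity checks.
#' @return An object of class `"phase_irf"` with the same grids.
#' @export
phase_irf <- function(hq, flip_sign = FALSE) {
  stopifnot(inherits(hq, "transient_irf"))
  h <- cumtrapz_from_zero(hq$h, hq$tau)
  if (flip_sign) h <- -h
  structure(list(h = h, tau = hq$tau, phases = hq$phases, dtau = hq$dtau,
                 channel = hq$channel, input = hq$input,
                 units = hq$units, T_bar = hq$T_bar, f0 = hq$f0),
            class = "phase_irf")
}

#' Compose the full time-domain phase-dependent impulse response
#'
#' Combines the transient response and the phase response with the cycle-mean
#' derivative:
#' `h_y(t_r, t_s) = f0 h_y~(t_r/T, t_s/T) + y0'(t_r/T) h_theta(t_r/T, t_s/T)`,
#' evaluated on a stimulus-phase by normalized-response-time grid.  The
#' second term converts an accumulated phase shift into the output deviation
#' it produces by advancing the baseline waveform.
#'
#' @param hy A `"transient_irf"` for the output channel.
#' @param htheta A `"phase_irf"` (from the phase-rate channel).
#' @param cm A `"cycle_mean"` containing the output channel.
#' @param dt Normalized response-time step in cycles (default 0.02).
#' @param horizon Response horizon after stimulus onset, cycles (default 3).
#' @param enforce_causality If `TRUE`, zero the pre-stimulus region; by
#'   default it is kept as a noise-floor diagnostic.
#' @return An object of class `"phirf"`.
#' @export
compose_phirf <- function(hy, htheta, cm, dt = 0.02, horizon = 3,
                          enforce_causality = FALSE) {
  stopifnot(inherits(hy, "transient_irf"), inherits(htheta, "phase_irf"),
            inherits(cm, "cycle_mean"))
  if (length(hy$phases) != length(htheta$phases) ||
      max(abs(hy$phases - htheta$phases)) > 1e-9 ||
      length(hy$tau) != length(htheta$tau))
    stop("compose_phirf(): transient and phase responses are on different grids")
  phases <- hy$phases
  tr <- seq(0, horizon + 1, by = dt)
  f0 <- hy$f0
  T_bar <- hy$T_bar
  y0p <- predict(cm, tr %% 1, channel = hy$channel, deriv = 1L)
  h <- matrix(0, length(tr), length(phases))
  for (m in seq_along(phases)) {
    tau_out <- tr - phases[m]
    hy_i <- stats::spline(hy$tau, hy$h[, m], xout = tau_out, method = "fmm")$y
    ht_i <- stats::spline(htheta$tau, htheta$h[, m], xout = tau_out, method = "fmm")$y
    h[, m] <- f0 * hy_i + y0p * ht_i
    if (enforce_causality) h[tau_out < 0, m] <- 0
  }
  structure(list(h = h, tr = tr, phases = phases, dt = dt, horizon = horizon,
                 T_bar = T_bar, f0 = f0,
                 baseline = predict(cm, tr %% 1, channel = hy$channel),
                 cycle_mean = cm, channel = hy$channel, input = hy$input,
                 units_out = unname(hy$units[hy$channel]),
                 units_in = unname(hy$units[hy$input]),
                 method = "htf"),
            class = "phirf")
}

#' Integrate a velocity-channel impulse response to position
#'
#' Cumulative time integral over response time starting at stimulus onset
#' (zero initial condition at onset); the pre-stimulus region is set to
#' zero.  Units lose a "/s".
#'
#' @param p A `"phirf"` for a velocity channel.
#' @return A `"phirf"` for the integrated (position) response.
#' @export
integrate_kinematic <- function(p) {
  stopifnot(inherits(p, "phirf"))
  out <- p
  dt_s <- p$dt * p$T_bar
  for (m in seq_along(p$phases)) {
    col <- p$h[, m]
    post <- p$tr >= p$phases[m] - 1e-9
    i0 <- which(post)[1]
    v <- col[post]
    ci <- c(0, cumsum((v[-1] + v[-length(v)]) / 2 * dt_s))
    col[] <- 0
    col[post] <- ci
    out$h[, m] <- col
  }
  out$units_out <- sub("/s$", "", p$units_out)
  out$baseline <- rep(NA_real_, length(p$tr))
  out
}

#' Extract one stimulus-phase column of a phase-dependent impulse response
#'
#' @param p A `"phirf"`.
#' @param stimulus_phase Phase in `[0,1)`; snapped to the nearest grid column.
#' @return List with `phase` (the grid phase used), `tr` and `h` (the
#'   response column).
#' @export
slice_phase <- function(p, stimulus_phase) {
  stopifnot(inherits(p, "phirf"))
  if (stimulus_phase < 0 || stimulus_phase >= 1)
    stop("`stimulus_phase` must be in [0, 1)")
  d <- abs(p$phases - stimulus_phase)
  d <- pmin(d, 1 - d)                      # phase is circular
  m <- which.min(d)
  list(phase = p$phases[m], tr = p$tr, h = p$h[, m])
}

#' Causality diagnostic of a phase-dependent impulse response
#'
#' Ratio of the mean absolute pre-stimulus response to the peak absolute
#' response; for a well-estimated system this is a noise-floor estimate and
#' should be small.
#'
#' @param p A `"phirf"`.
#' @return Scalar ratio.
#' @export
causality_ratio <- function(p) {
  stopifnot(inherits(p, "phirf"))
  pre <- numeric(0)
  for (m in seq_along(p$phases))
    pre <- c(pre, p$h[p$tr < p$phases[m] - 1e-9, m])
  if (length(pre) == 0L) return(NA_real_)
  mean(abs(pre)) / max(abs(p$h))
}

#' @export
print.phirf <- function(x, ...) {
  cat(sprintf("<phiIRF> %s -> %s [%s per %s*s], %d stimulus phases x %d response times\n",
              x$input, x$channel, x$units_out, x$units_in,
              length(x$phases), length(x$tr)))
  cat(sprintf("  T_bar = %.3f s, horizon = %g cycles, peak |h| = %.3g, method = %s\n",
              x$T_bar, x$horizon, max(abs(x$h)), x$method))
  invisible(x)
}

#' @export
summary.phirf <- function(object, ...) {
  pk <- which(abs(object$h) == max(abs(object$h)), arr.ind = TRUE)[1, ]
  cat(sprintf("phiIRF of %s to an impulse in %s\n", object$channel, object$input))
  cat(sprintf("  grid: %d stimulus phases, response time 0..%g cycles (step %g)\n",
              length(object$phases), max(object$tr), object$dt))
  cat(sprintf("  mean cycle period: %.3f s\n", object$T_bar))
  cat(sprintf("  peak response %.4g %s/(%s*s) at stimulus phase %.2f, response time %.2f cycles\n",
              object$h[pk[1], pk[2]], object$units_out, object$units_in,
              object$phases[pk[2]], object$tr[pk[1]]))
  cr <- causality_ratio(object)
  if (is.finite(cr))
    cat(sprintf("  pre-stimulus noise floor: %.1f%% of peak\n", 100 * cr))
  invisible(object)
}

#' @export
coef.phirf <- function(object, ...) {
  structure(object$h, dimnames = list(
    response_time = formatC(object$tr, format = "g"),
    stimulus_phase = formatC(object$phases, format = "g")))
}

#' Heatmap of a phase-dependent impulse response
#'
#' Stimulus phase on the x-axis, normalized response time on the y-axis,
#' with the diagonal stimulus-onset line.
#'
#' @param x A `"phirf"`.
#' @param zlim Symmetric color limits; defaults to the absolute maximum.
#' @param ... Passed to [graphics::image()].
#' @export
plot.phirf <- function(x, zlim = NULL, ...) {
  if (is.null(zlim)) zlim <- c(-1, 1) * max(abs(x$h))
  pal <- grDevices::hcl.colors(65, "Blue-Red 3")
  graphics::image(x$phases, x$tr, t(x$h), zlim = zlim, col = pal,
                  xlab = "stimulus phase (cycles)",
                  ylab = "normalized response time (cycles)",
                  main = sprintf("phiIRF: %s -> %s", x$input, x$channel), ...)
  graphics::abline(0, 1, lwd = 2)
  graphics::abline(1, 1, lty = 2)
  invisible(x)
}

#' Normalized RMS difference between two impulse-response estimates
#'
#' Root-mean-square difference over the post-stimulus region (lags in
#' `window` cycles after onset), divided by the RMS of the reference over
#' the same region.
#'
#' @param est,ref `"phirf"` objects on identical grids.
#' @param window Lag window in cycles after onset (default `c(0, 3)`).
#' @return Scalar normalized RMSE.
#' @export
phirf_nrmse <- function(est, ref, window = c(0, 3)) {
  stopifnot(inherits(est, "phirf"), inherits(ref, "phirf"))
  if (length(est$tr) != length(ref$tr) || length(est$phases) != length(ref$phases))
    stop("phirf_nrmse(): grids differ")
  num <- 0; den <- 0
  for (m in seq_along(ref$phases)) {
    lag <- est$tr - ref$phases[m]
    sel <- lag >= window[1] - 1e-9 & lag <= window[2] + 1e-9
    num <- num + sum((est$h[sel, m] - ref$h[sel, m])^2)
    den <- den + sum(ref$h[sel, m]^2)
  }
  sqrt(num / den)
}
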