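#' Fit a phase-dependent impulse response function
#'
#' Estimates the phase-dependent impulse response function (phiIRF) of one
#' response channel to a continuous perturbation from one or more trials of
#' a single subject.  Each trial supplies the perturbation input, the output
#' channels, and cycle-event (heel-strike) times.  The procedure is:
#' (1) causal phase estimation from the events ([approximate_phase()]);
#' (2) resampling of input, response and phase rate from time to phase
#' ([to_phase_domain()]); (3) cycle-mean removal ([cycle_mean()]);
#' (4) Welch PSD / double-frequency CSD and harmonic transfer function modes
#' for both the transient and the phase-rate response, pooled across trials
#' ([welch_psd_csd()], [pool_spectra()], [compute_htf()]); (5) inverse
#' transform to transient and phase impulse responses ([htf_to_irf()],
#' [phase_irf()]); (6) composition with the cycle-mean derivative into the
#' time-domain phiIRF ([compose_phirf()]).  The phase response term accounts
#' for phase resetting of the underlying oscillator, which a strictly
#' time-periodic analysis would miss.
#'
#' @param trials A single trial or list of trials; each trial is a list with
#'   `input` (a `"phirf_ts"`), `channels` (named list of `"phirf_ts"`) and
#'   `events` (numeric vector of seconds).
#' @param response Name of the response channel in `channels`.
#' @param d Phase-filter rate constant, 1/s (default 2).
#' @param dphi Phase grid spacing in cycles (default 1/128).
#' @param M Harmonic order of the cycle mean (default 20).
#' @param window_cycles,overlap Welch window length (cycles) and overlap.
#' @param k_max Largest HTF mode (default 10).
#' @param f_max Top of the analysis band in cycles^-1 (default 10).
#' @param taper_frac,mode_taper Band-edge and mode tapers (see [htf_to_irf()]).
#' @param n_phases Number of stimulus phases (default 50).
#' @param dt Normalized response-time step in cycles (default 0.02).
#' @param horizon Response horizon in cycles after onset (default 3).
#' @param flip_phase_sign Integrate the phase response with the opposite
#'   orientation (see [phase_irf()]).
#' @param enforce_causality Zero the pre-stimulus region (default `FALSE`).
#' @return An object of class `"phirf"` (see [compose_phirf()]) with
#'   additional diagnostics: pooled segment count, causality ratio, and the
#'   pooled HTF estimate.
#' @seealso [predict.phirf()], [slice_phase()], [phirf_group()],
#'   [oracle_phirf()]
#' @export
phirf <- function(trials, response, d = 2, dphi = 1 / 128, M = 20,
                  window_cycles = 40, overlap = 0.5, k_max = 10, f_max = 10,
                  taper_frac = 0.2, mode_taper = 2, n_phases = 50, dt = 0.02,
                  horizon = 3, flip_phase_sign = FALSE,
                  enforce_causality = FALSE) {
  if (!is.null(trials$input)) trials <- list(trials)
  if (length(trials) == 0L) stop("no trials supplied")
  phases <- (seq_len(n_phases) - 1) / n_phases

  ses <- vector("list", length(trials))
  cms <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (is.null(tr$input) || is.null(tr$channels) || is.null(tr$events))
      stop("each trial needs `input`, `channels`, `events`")
    if (!response %in% names(tr$channels))
      stop("response channel not found in trial: ", response)
    st <- stride_stats(tr$events)
    pm <- approximate_phase(tr$events, ts_times(tr$input), d = d, stats = st)
    chans <- c(list(.u = tr$input), tr$channels[response])
    pds <- to_phase_domain(pm, chans, dphi = dphi)
    dec <- cycle_mean(pds, M = M, channels = response)
    cms[[i]] <- dec$mean
    ses[[i]] <- welch_psd_csd(dec$dev, input = ".u",
                              outputs = c(response, ".q"),
                              window_cycles = window_cycles, overlap = overlap,
                              k_max = k_max, f_max = f_max)
  }
  se <- pool_spectra(ses)
  cm <- pool_cycle_means(cms)
  se$T_bar <- cm$T_bar
  se$f0 <- 1 / cm$T_bar
  htf <- compute_htf(se)
  hy <- htf_to_irf(htf, channel = response, phases = phases,
                   tau_range = c(-1, horizon + 1),
                   taper_frac = taper_frac, mode_taper = mode_taper)
  hq <- htf_to_irf(htf, channel = ".q", phases = phases,
                   tau_range = c(-1, horizon + 1),
                   taper_frac = taper_frac, mode_taper = mode_taper)
  ht <- phase_irf(hq, flip_sign = flip_phase_sign)
  fit <- compose_phirf(hy, ht, cm, dt = dt, horizon = horizon,
                       enforce_causality = enforce_causality)
  fit$htf <- htf
  fit$h_theta <- ht
  fit$n_segments <- se$n_segments
  fit$n_trials <- length(trials)
  fit$call <- match.call()
  fit
}

#' Predict the response to an arbitrary small perturbation
#'
#' Linearized response reconstruction: the predicted output is the baseline
#' periodic waveform plus the convolution of the phiIRF with the
#' perturbation,
#' `y(t_r) = y0(t_r) + int h(t_r, t_s) u(t_s) dt_s`.
#' Because the underlying oscillator can be phase-reset, the kernel does not
#' decay at long lags: its long-lag limit is the baseline derivative scaled
#' by the accumulated phase response.  Contributions from stimuli older than
#' the kernel horizon are therefore carried by a running phase-shift
#' accumulator using the kernel's limiting phase response (disable with
#' `extend_phase = FALSE` to truncate strictly at the horizon).
#'
#' @param object A `"phirf"`.
#' @param u A `"phirf_ts"` perturbation, with `t = 0` at a cycle event
#'   (phase zero) and duration of at least one cycle.
#' @param type `"response"` (baseline + deviation) or `"deviation"`.
#' @param extend_phase Carry phase shifts beyond the kernel horizon
#'   (default `TRUE`).
#' @param ... Unused.
#' @return A `"phirf_ts"` sampled at `dt * T_bar` steps.
#' @export
predict.phirf <- function(object, u, type = c("response", "deviation"),
                          extend_phase = TRUE, ...) {
  type <- match.arg(type)
  stopifnot(inherits(u, "phirf_ts"))
  T_bar <- object$T_bar
  if (length(u$values) / u$rate < T_bar)
    stop("predict.phirf(): perturbation shorter than one cycle period")
  dt_s <- object$dt * T_bar
  tt <- ts_times(u)
  tout <- seq(tt[1], tt[length(tt)], by = dt_s)
  uu <- stats::spline(tt, u$values, xout = tout, method = "fmm")$y
  n <- length(tout)
  nph <- length(object$phases)
  L <- round(object$horizon / object$dt)     # lags 0..L within the horizon

  # kernel by lag and stimulus-phase index: K[l+1, m] = h(ts + l dt, ts)
  K <- matrix(0, L + 1L, nph)
  ratio <- round((1 / object$dt) / nph)      # tr-grid steps per phase step
  for (m in seq_len(nph)) {
    i0 <- which.min(abs(object$tr - object$phases[m]))
    K[, m] <- object$h[i0:(i0 + L), m]
  }
  ph_idx <- (round(tout / dt_s) %% (1 / object$dt)) %/% ratio + 1L

  dev <- numeric(n)
  for (l in 0:L) {
    src <- seq_len(n - l)
    dev[src + l] <- dev[src + l] + K[l + 1L, ph_idx[src]] * uu[src] * dt_s
  }

  if (extend_phase) {
    # limiting phase response per stimulus phase (mean over the last cycle
    # of the lag horizon), converted to output via the baseline derivative
    ht <- object$h_theta
    if (!is.null(ht)) {
      hbar <- numeric(nph)
      for (m in seq_len(nph)) {
        sel <- ht$tau >= object$horizon - 1 & ht$tau <= object$horizon
        hbar[m] <- mean(ht$h[sel, m])
      }
      shift <- cumsum(hbar[ph_idx] * uu * dt_s)   # accumulated phase (cycles)
      old <- rep(0, n)
      if (n > L + 1L) old[(L + 2L):n] <- shift[1:(n - L - 1L)]
      y0p <- predict(object$cycle_mean, (tout / T_bar) %% 1,
                     channel = object$channel, deriv = 1L)
      dev <- dev + y0p * old
    }
  }

  if (type == "deviation") {
    out <- dev
  } else {
    y0 <- predict(object$cycle_mean, (tout / T_bar) %% 1, channel = object$channel)
    out <- y0 + dev
  }
  time_series(out, rate = 1 / dt_s, start = tout[1], units = object$units_out)
}
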