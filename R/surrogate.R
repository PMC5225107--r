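#' Harmonic function of phase
#'
#' Compact representation of a smooth 1-periodic function
#' `a0 + sum_m ac[m] cos(2 pi m theta) + as[m] sin(2 pi m theta)`,
#' used for baseline waveforms, phase-response gains and phase-modulated
#' system matrices of the surrogate walker.
#'
#' @param a0 Constant term.
#' @param ac,as Cosine and sine coefficient vectors (padded to equal length).
#' @return An object of class `"harmonics"`.
#' @export
harmonics <- function(a0 = 0, ac = numeric(0), as = numeric(0)) {
  M <- max(length(ac), length(as))
  length(ac) <- M; length(as) <- M
  ac[is.na(ac)] <- 0; as[is.na(as)] <- 0
  structure(list(a0 = a0, ac = ac, as = as), class = "harmonics")
}

#' Evaluate a harmonic function of phase
#'
#' @param h A `"harmonics"` object.
#' @param theta Phases in cycles.
#' @param deriv 0 for the value, 1 for the derivative per cycle.
#' @return Numeric vector.
#' @export
eval_harmonics <- function(h, theta, deriv = 0L) {
  eval_harmonics_coef(h, theta, deriv = deriv)
}

scale_harmonics <- function(h, s) {
  harmonics(h$a0 * s, h$ac * s, h$as * s)
}

#' Limit-cycle walker surrogate model
#'
#' A configurable noise-perturbed limit-cycle oscillator used as synthetic
#' ground truth.  Phase evolves as
#' `theta' = f0 + alpha(theta) u + phase noise` (the phase-response gain
#' `alpha` produces phase resetting), a transient state evolves as
#' `x' = A(theta) x + B(theta) u + process noise`, and each output channel is
#' `y = y0(theta) + C(theta) x + measurement noise`.  All phase dependence is
#' harmonic.  Cycle events are the upward integer crossings of `theta`.
#'
#' @param f0 Unperturbed cycle frequency in Hz.
#' @param alpha `"harmonics"`: phase-response gain, cycles/s per input unit.
#' @param dynamics List with `A0` (m x m matrix), `Ac`, `As` (lists of m x m
#'   matrices per harmonic order), and `B0`, `Bc`, `Bs` (m-vectors likewise).
#' @param channels Named list; each channel is a list with `y0`
#'   (`"harmonics"`), `C` (list of `"harmonics"`, one per state; `NULL` for a
#'   pure phase-driven channel), `sd` (measurement noise SD), `units`, and
#'   optional `rectify = TRUE` for nonnegative envelope-like channels.
#' @param phase_sd Phase diffusion intensity, cycles/sqrt(s).
#' @param process_sd Process noise intensity per state, units/sqrt(s).
#' @param rate Simulation rate, samples/s (default 120).
#' @param spring Optional `list(k, u0, channel)`: drive the dynamics with the
#'   spring force `F(t) = k (u(t) - y(t) - u0)` instead of `u` itself, where
#'   `y` is the named position channel.
#' @return An object of class `"surrogate_model"`.
#' @export
surrogate_model <- function(f0, alpha, dynamics, channels,
                            phase_sd = 0, process_sd = 0, rate = 120,
                            spring = NULL) {
  m <- nrow(as.matrix(dynamics$A0))
  stopifnot(f0 > 0, rate > 0, inherits(alpha, "harmonics"))
  A0 <- as.matrix(dynamics$A0)
  ev <- eigen(A0, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("surrogate_model(): time-averaged A must be stable (eigenvalue real parts < 0)")
  process_sd <- rep_len(process_sd, m)
  structure(list(f0 = f0, alpha = alpha, dynamics = dynamics,
                 channels = channels, phase_sd = phase_sd,
                 process_sd = process_sd, rate = rate, spring = spring,
                 m = m),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("<surrogate walker> f0 = %.3f Hz, %d transient state(s), channels: %s\n",
              x$f0, x$m, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Default walker-like surrogate configuration
#'
#' A walking-like limit cycle at `f0 = 1/1.04` Hz with three output channels:
#' a trunk-orientation-like angle (deg, dominated by the second stride
#' harmonic), an A-P-velocity-like channel (cm/s) and a nonnegative EMG-like
#' envelope.  The input is a visual-velocity-like perturbation (deg/s).
#' Phase-response gain and transient dynamics are phase-modulated, and noise
#' intensities are set to plausible human-locomotor values: phase diffusion
#' giving a stride-time CV of about 1%, and kinematic measurement noise of
#' 0.1 deg.
#'
#' @param phase_sd,trunk_sd Override the phase-diffusion and trunk
#'   measurement-noise intensities.
#' @param alpha_scale Scale factor on the phase-response gain (0 disables
#'   phase resetting).
#' @return A `"surrogate_model"`.
#' @export
walker_model <- function(phase_sd = 0.01, trunk_sd = 0.1, alpha_scale = 1) {
  surrogate_model(
    f0 = 1 / 1.04,
    alpha = scale_harmonics(harmonics(0.02, ac = 0, as = 0.016), alpha_scale),
    dynamics = list(
      A0 = matrix(-3), Ac = list(matrix(1)), As = list(matrix(0)),
      B0 = 0.3, Bc = list(0), Bs = list(0.15)),
    channels = list(
      trunk = list(
        y0 = harmonics(3, ac = c(0.6, 1.2, 0.25), as = c(-0.4, 0.9, -0.15)),
        C = list(harmonics(1, ac = 0.3, as = 0)),
        sd = trunk_sd, units = "deg"),
      ap_vel = list(
        y0 = harmonics(0, ac = c(-2, 6), as = c(1.5, -2)),
        C = list(harmonics(2, ac = 0, as = 0.5)),
        sd = 0.5, units = "cm/s"),
      emg = list(
        y0 = harmonics(0.5, ac = c(-0.25, 0.15), as = c(0.3, -0.1)),
        C = list(harmonics(0.2, ac = 0.1, as = 0)),
        sd = 0.05, units = "a.u.", rectify = TRUE)),
    phase_sd = phase_sd, process_sd = 0.1, rate = 120)
}

#' Pure phase-oscillator surrogate
#'
#' A surrogate with no transient dynamics: the perturbation acts only
#' through the phase-response gain, so the entire response is a (possibly
#' permanent) shift of the baseline waveform.  Used to isolate the
#' phase-resetting path of the estimator.
#'
#' @param f0 Cycle frequency (Hz).
#' @param alpha `"harmonics"` phase-response gain.
#' @param y0 `"harmonics"` baseline waveform of the single channel `y`.
#' @param phase_sd Phase diffusion (cycles/sqrt(s)).
#' @param meas_sd Measurement noise SD.
#' @return A `"surrogate_model"`.
#' @export
phase_oscillator_model <- function(f0 = 1 / 1.04,
                                   alpha = harmonics(0.02, ac = 0, as = 0.016),
                                   y0 = harmonics(0, ac = c(1, 0.4), as = c(0, 0.2)),
                                   phase_sd = 0, meas_sd = 0) {
  surrogate_model(
    f0 = f0, alpha = alpha,
    dynamics = list(A0 = matrix(-1), Ac = list(matrix(0)), As = list(matrix(0)),
                    B0 = 0, Bc = list(0), Bs = list(0)),
    channels = list(y = list(y0 = y0, C = NULL, sd = meas_sd, units = "a.u.")),
    phase_sd = phase_sd, process_sd = 0, rate = 120)
}

# evaluate A(theta) x + B(theta) u for vectors of theta (vectorized, m small)
eval_dyn_matrices <- function(dyn, theta) {
  m <- nrow(as.matrix(dyn$A0))
  nt <- length(theta)
  A <- array(rep(as.matrix(dyn$A0), each = nt), dim = c(nt, m, m))
  B <- matrix(rep(dyn$B0, each = nt), nt, m)
  H <- length(dyn$Ac)
  for (j in seq_len(H)) {
    cj <- cos(2 * pi * j * theta); sj <- sin(2 * pi * j * theta)
    A <- A + outer(cj, as.matrix(dyn$Ac[[j]])) + outer(sj, as.matrix(dyn$As[[j]]))
    B <- B + outer(cj, dyn$Bc[[j]]) + outer(sj, dyn$Bs[[j]])
  }
  list(A = A, B = B)
}

#' Simulate one trial of the surrogate walker
#'
#' Integrates the phase equation and the transient dynamics with fixed-step
#' 4th-order Runge-Kutta at the model rate, adding Gaussian noise increments
#' per step; outputs and events (integer phase crossings, located by linear
#' interpolation) are deterministic given the seed.
#'
#' @param model A `"surrogate_model"`.
#' @param u A `"phirf_ts"` perturbation at the model rate.
#' @param seed Integer seed, or `NULL`.
#' @param theta0,x0 Initial phase (cycles) and transient state.
#' @return A trial record: list with `input`, `channels` (named list of
#'   `"phirf_ts"`), `events` (seconds), `theta` (true phase per sample),
#'   `seed`.
#' @export
simulate_trial <- function(model, u, seed = NULL, theta0 = 0, x0 = NULL) {
  stopifnot(inherits(model, "surrogate_model"), inherits(u, "phirf_ts"))
  if (abs(u$rate - model$rate) > 1e-9)
    stop("simulate_trial(): perturbation rate must match the model rate")
  if (!is.null(seed)) set.seed(seed)
  n <- length(u$values)
  h <- 1 / model$rate
  m <- model$m
  if (is.null(x0)) x0 <- numeric(m)
  uu <- u$values
  umid <- c((uu[-n] + uu[-1]) / 2, uu[n])
  if (!is.null(model$spring))
    return(simulate_trial_spring(model, u, theta0, x0, seed))

  a0 <- model$alpha$a0; aac <- model$alpha$ac; aas <- model$alpha$as
  Ma <- length(aac); wv <- 2 * pi * seq_len(Ma)
  alpha_at <- function(th) a0 + sum(aac * cos(wv * th)) + sum(aas * sin(wv * th))

  f0 <- model$f0
  theta <- numeric(n)
  theta[1] <- theta0
  ph_noise <- if (model$phase_sd > 0) stats::rnorm(n - 1, sd = model$phase_sd * sqrt(h)) else numeric(n - 1)
  th <- theta0
  for (k in seq_len(n - 1L)) {
    u1 <- uu[k]; u2 <- umid[k]; u3 <- uu[k + 1L]
    k1 <- f0 + alpha_at(th) * u1
    k2 <- f0 + alpha_at(th + h / 2 * k1) * u2
    k3 <- f0 + alpha_at(th + h / 2 * k2) * u2
    k4 <- f0 + alpha_at(th + h * k3) * u3
    th <- th + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4) + ph_noise[k]
    theta[k + 1L] <- th
  }

  # transient dynamics: linear time-varying given theta(t); precompute
  # matrices at sample and midpoint phases, then RK4 with noise increments
  thmid <- (theta[-n] + theta[-1]) / 2
  Ds <- eval_dyn_matrices(model$dynamics, theta)
  Dm <- eval_dyn_matrices(model$dynamics, thmid)
  x <- matrix(0, n, m)
  x[1, ] <- x0
  pn <- matrix(0, n - 1L, m)
  if (any(model$process_sd > 0))
    pn <- matrix(stats::rnorm((n - 1L) * m), n - 1L, m) *
      rep(model$process_sd * sqrt(h), each = n - 1L)
  xv <- x0
  for (k in seq_len(n - 1L)) {
    A1 <- matrix(Ds$A[k, , ], m, m); B1 <- Ds$B[k, ]
    A2 <- matrix(Dm$A[k, , ], m, m); B2 <- Dm$B[k, ]
    A3 <- matrix(Ds$A[k + 1L, , ], m, m); B3 <- Ds$B[k + 1L, ]
    u1 <- uu[k]; u2 <- umid[k]; u3 <- uu[k + 1L]
    k1 <- A1 %*% xv + B1 * u1
    k2 <- A2 %*% (xv + h / 2 * k1) + B2 * u2
    k3 <- A2 %*% (xv + h / 2 * k2) + B2 * u2
    k4 <- A3 %*% (xv + h * k3) + B3 * u3
    xv <- xv + h / 6 * as.numeric(k1 + 2 * k2 + 2 * k3 + k4) + pn[k, ]
    if (any(!is.finite(xv)) || sqrt(sum(xv^2)) > 1e6)
      stop("simulate_trial(): transient state diverged; unstable configuration")
    x[k + 1L, ] <- xv
  }

  channels <- list()
  for (nm in names(model$channels)) {
    ch <- model$channels[[nm]]
    y <- eval_harmonics(ch$y0, theta)
    if (!is.null(ch$C))
      for (i in seq_len(m)) y <- y + eval_harmonics(ch$C[[i]], theta) * x[, i]
    if (!is.null(ch$sd) && ch$sd > 0) y <- y + stats::rnorm(n, sd = ch$sd)
    if (isTRUE(ch$rectify)) y <- pmax(y, 0)
    channels[[nm]] <- time_series(y, model$rate, u$start, ch$units, u$valid)
  }

  k_cross <- which(floor(theta[-1] + 1e-12) > floor(theta[-n] + 1e-12))
  tt <- ts_times(u)
  events <- vapply(k_cross, function(k) {
    target <- ceiling(theta[k] - 1e-12)
    tt[k] + h * (target - theta[k]) / (theta[k + 1L] - theta[k])
  }, numeric(1))

  list(input = u, channels = channels, events = events, theta = theta,
       seed = seed)
}

# joint integration used when the spring coupling is enabled: the drive is
# the spring force F(t) = k (u(t) - y(t) - u0), where y is the named
# position channel, so phase and transient state must be advanced together
simulate_trial_spring <- function(model, u, theta0, x0, seed = NULL) {
  sp <- model$spring
  ch <- model$channels[[sp$channel]]
  if (is.null(ch)) stop("spring$channel not found: ", sp$channel)
  n <- length(u$values)
  h <- 1 / model$rate
  m <- model$m
  uu <- u$values
  umid <- c((uu[-n] + uu[-1]) / 2, uu[n])
  dyn <- model$dynamics
  Hn <- length(dyn$Ac)
  ypos <- function(th, x) {
    y <- eval_harmonics(ch$y0, th)
    if (!is.null(ch$C)) for (i in seq_len(m)) y <- y + eval_harmonics(ch$C[[i]], th) * x[i]
    y
  }
  deriv <- function(th, x, uv) {
    Fdrv <- sp$k * (uv - ypos(th, x) - sp$u0)
    A <- as.matrix(dyn$A0); B <- dyn$B0
    for (j in seq_len(Hn)) {
      cj <- cos(2 * pi * j * th); sj <- sin(2 * pi * j * th)
      A <- A + cj * as.matrix(dyn$Ac[[j]]) + sj * as.matrix(dyn$As[[j]])
      B <- B + cj * dyn$Bc[[j]] + sj * dyn$Bs[[j]]
    }
    list(dth = model$f0 + eval_harmonics(model$alpha, th) * Fdrv,
         dx = as.numeric(A %*% x + B * Fdrv), F = Fdrv)
  }
  theta <- numeric(n); x <- matrix(0, n, m); Fvec <- numeric(n)
  th <- theta0; xv <- x0
  theta[1] <- th; x[1, ] <- xv
  Fvec[1] <- deriv(th, xv, uu[1])$F
  ph_noise <- if (model$phase_sd > 0) stats::rnorm(n - 1, sd = model$phase_sd * sqrt(h)) else numeric(n - 1)
  pn <- matrix(0, n - 1L, m)
  if (any(model$process_sd > 0))
    pn <- matrix(stats::rnorm((n - 1L) * m), n - 1L, m) *
      rep(model$process_sd * sqrt(h), each = n - 1L)
  for (k in seq_len(n - 1L)) {
    k1 <- deriv(th, xv, uu[k])
    k2 <- deriv(th + h / 2 * k1$dth, xv + h / 2 * k1$dx, umid[k])
    k3 <- deriv(th + h / 2 * k2$dth, xv + h / 2 * k2$dx, umid[k])
    k4 <- deriv(th + h * k3$dth, xv + h * k3$dx, uu[k + 1L])
    th <- th + h / 6 * (k1$dth + 2 * k2$dth + 2 * k3$dth + k4$dth) + ph_noise[k]
    xv <- xv + h / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx) + pn[k, ]
    if (any(!is.finite(xv)) || sqrt(sum(xv^2)) > 1e6)
      stop("simulate_trial(): transient state diverged; unstable configuration")
    theta[k + 1L] <- th; x[k + 1L, ] <- xv
    Fvec[k + 1L] <- deriv(th, xv, uu[k + 1L])$F
  }
  channels <- list()
  for (nm in names(model$channels)) {
    chn <- model$channels[[nm]]
    y <- eval_harmonics(chn$y0, theta)
    if (!is.null(chn$C))
      for (i in seq_len(m)) y <- y + eval_harmonics(chn$C[[i]], theta) * x[, i]
    if (!is.null(chn$sd) && chn$sd > 0) y <- y + stats::rnorm(n, sd = chn$sd)
    if (isTRUE(chn$rectify)) y <- pmax(y, 0)
    channels[[nm]] <- time_series(y, model$rate, u$start, chn$units, u$valid)
  }
  k_cross <- which(floor(theta[-1] + 1e-12) > floor(theta[-n] + 1e-12))
  tt <- ts_times(u)
  events <- vapply(k_cross, function(k) {
    target <- ceiling(theta[k] - 1e-12)
    tt[k] + h * (target - theta[k]) / (theta[k + 1L] - theta[k])
  }, numeric(1))
  list(input = u, channels = channels, events = events, theta = theta,
       force = time_series(Fvec, model$rate, u$start, "N", u$valid),
       seed = seed)
}

#' Ground-truth phiIRF by brute-force impulse experiments
#'
#' For each stimulus phase, simulates the noise-free surrogate with and
#' without a small input pulse from identical on-cycle initial conditions;
#' the phiIRF column is the output difference divided by the pulse area,
#' sampled on the normalized-response-time grid.  A convergence check
#' repeats each column with half the pulse area and flags columns that
#' change by more than 1%.
#'
#' @param model A `"surrogate_model"`.
#' @param channel Output channel name.
#' @param phases Stimulus phases in `[0,1)` (default 50).
#' @param pulse_area Pulse area in input-units * s (default 1e-3).
#' @param dt,horizon Normalized response-time step and horizon (cycles).
#' @return A `"phirf"` object with `method = "oracle"`; attribute
#'   `"converged"` flags per-column convergence.
#' @export
oracle_phirf <- function(model, channel = names(model$channels)[1],
                         phases = (0:49) / 50, pulse_area = 1e-3,
                         dt = 0.02, horizon = 3) {
  stopifnot(inherits(model, "surrogate_model"))
  noiseless <- model
  noiseless$phase_sd <- 0
  noiseless$process_sd <- rep(0, model$m)
  for (nm in names(noiseless$channels)) noiseless$channels[[nm]]$sd <- 0

  T0 <- 1 / model$f0
  tr <- seq(0, horizon + 1, by = dt)
  dur <- (horizon + 1.5) * T0
  nsim <- ceiling(dur * model$rate)
  tt <- (seq_len(nsim) - 1) / model$rate
  ch <- noiseless$channels[[channel]]
  base <- eval_harmonics(ch$y0, model$f0 * tr * T0)  # x = 0 on the limit cycle
  base_sim <- eval_harmonics(ch$y0, model$f0 * tt)

  col_for <- function(ph, area) {
    uvec <- numeric(nsim)
    # split the pulse over two samples so its centroid is exactly t_s
    pos <- ph * T0 * model$rate
    i_s <- floor(pos) + 1L
    frac <- pos - (i_s - 1L)
    uvec[i_s] <- (1 - frac) * area * model$rate
    uvec[i_s + 1L] <- frac * area * model$rate
    u <- time_series(uvec, model$rate, 0, "input")
    sim <- simulate_trial(noiseless, u, seed = NULL, theta0 = 0)
    # interpolate the (deviation / area) with a local C1 interpolant so the
    # pre-stimulus region stays exactly zero
    d <- (sim$channels[[channel]]$values - base_sim) / area
    stats::splinefun(tt, d, method = "monoH.FC")(tr * T0)
  }

  h <- matrix(0, length(tr), length(phases))
  converged <- rep(TRUE, length(phases))
  for (mth in seq_along(phases)) {
    c1 <- col_for(phases[mth], pulse_area)
    c2 <- col_for(phases[mth], pulse_area / 2)
    h[, mth] <- c2                                  # smaller pulse = closer to the limit
    scale <- max(abs(c2))
    if (scale > 0 && max(abs(c2 - c1)) / scale > 0.01) converged[mth] <- FALSE
  }
  structure(list(h = h, tr = tr, phases = phases, dt = dt, horizon = horizon,
                 T_bar = T0, f0 = model$f0,
                 baseline = base,
                 cycle_mean = NULL, channel = channel, input = "u",
                 units_out = ch$units, units_in = "input",
                 method = "oracle", converged = converged),
            class = "phirf")
}

#' Generate a multi-subject surrogate cohort
#'
#' Emulates a perturbation-walking study: per-subject parameter jitter
#' (cycle frequency, waveform/gain amplitudes), independent perturbation
#' realizations and noise per trial.  Trial `t = 0` is a cycle event and the
#' first and last `ramp` seconds of each trial are marked invalid for
#' analysis, mirroring ramped deployment.
#'
#' @param model A `"surrogate_model"` (the cohort mean).
#' @param n_subjects,n_trials Cohort size.
#' @param spec A `"perturbation_spec"` for the input signal.
#' @param seed Integer seed for the whole cohort.
#' @param input `"velocity"` to drive and analyze with the derivative of the
#'   generated signal (the convention for visual scene perturbations),
#'   `"position"` for the signal itself.
#' @param jitter List with `f0_sd` (Hz) and `amp_sd` (relative SD applied to
#'   waveform, output-gain and phase-response amplitudes).  Set both to 0
#'   for a homogeneous cohort sharing one true phiIRF.
#' @return List of subjects; each subject is a list with `trials` (list of
#'   trial records) and `model` (the jittered subject model).
#' @export
make_cohort <- function(model, n_subjects, n_trials,
                        spec = visual_perturbation_spec(rate = model$rate),
                        seed = 1, input = c("velocity", "position"),
                        jitter = list(f0_sd = 0.04, amp_sd = 0.1)) {
  input <- match.arg(input)
  stopifnot(inherits(model, "surrogate_model"))
  set.seed(seed)
  subj_seeds <- sample.int(2^30, n_subjects)
  cohort <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(subj_seeds[s])
    sm <- model
    if (jitter$f0_sd > 0)
      sm$f0 <- max(0.5 * model$f0, model$f0 + stats::rnorm(1, sd = jitter$f0_sd))
    if (jitter$amp_sd > 0) {
      g <- function() max(0.2, 1 + stats::rnorm(1, sd = jitter$amp_sd))
      sm$alpha <- scale_harmonics(sm$alpha, g())
      for (nm in names(sm$channels)) {
        sc <- g()
        sm$channels[[nm]]$y0 <- scale_harmonics(sm$channels[[nm]]$y0, sc)
        if (!is.null(sm$channels[[nm]]$C))
          sm$channels[[nm]]$C <- lapply(sm$channels[[nm]]$C, scale_harmonics, s = g())
      }
    }
    trial_seeds <- sample.int(2^30, n_trials)
    trials <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      u <- generate_perturbation(spec, seed = trial_seeds[tr])
      if (input == "velocity") u <- differentiate(u)
      tvec <- ts_times(u)
      u$valid <- tvec >= spec$ramp & tvec <= spec$duration - spec$ramp
      trials[[tr]] <- simulate_trial(sm, u, seed = trial_seeds[tr] + 1L)
    }
    cohort[[s]] <- list(trials = trials, model = sm)
  }
  cohort
}

#' Fit phiIRFs for every subject of a cohort
#'
#' @param cohort Output of [make_cohort()] (or [load_dataset()]).
#' @param response Response channel name.
#' @param ... Passed to [phirf()].
#' @return A `"phirf_group"` (see [phirf_group()]).
#' @export
phirf_cohort <- function(cohort, response, ...) {
  fits <- lapply(cohort, function(s) phirf(s$trials, response = response, ...))
  phirf_group(fits)
}
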