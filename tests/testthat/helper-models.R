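# shared builders for surrogate-based tests

# first-order LTI surrogate: no phase resetting, constant dynamics
lti_model <- function(lambda = 3, f0 = 1 / 1.04) {
  surrogate_model(
    f0 = f0, alpha = harmonics(0),
    dynamics = list(A0 = matrix(-lambda), Ac = list(matrix(0)), As = list(matrix(0)),
                    B0 = 1, Bc = list(0), Bs = list(0)),
    channels = list(y = list(y0 = harmonics(1, ac = c(0.5, 1), as = c(0.2, -0.4)),
                             C = list(harmonics(1)), sd = 0, units = "a.u.")),
    phase_sd = 0, process_sd = 0, rate = 120)
}

# visual perturbation chain scaled in amplitude; `scale` multiplies amplitude
# (PSD scales with scale^2)
visual_spec_scaled <- function(scale = 1, rate = 120, duration = 250) {
  perturbation_spec(
    kind = "visual", psd_level = 150 * scale^2,
    filter_chain = list(
      list(family = "firstorder", order = 1L, cutoff = 0.02),
      list(family = "butter", order = 2L, cutoff = 5)),
    duration = duration, ramp = 5, rate = rate)
}

# one simulated trial driven by the visual-velocity signal, ramps masked
sim_visual_trial <- function(model, seed, scale = 1, duration = 250) {
  u <- differentiate(generate_perturbation(
    visual_spec_scaled(scale, rate = model$rate, duration = duration), seed = seed))
  tv <- ts_times(u)
  u$valid <- tv >= 5 & tv <= duration - 5
  simulate_trial(model, u, seed = seed + 1L)
}

# synthetic phase-domain record for direct spectral tests
make_pds <- function(u, z = NULL, q = NULL, dphi = 1 / 128, valid = NULL) {
  n <- length(u)
  grid <- seq(0, by = dphi, length.out = n)
  channels <- list(.u = u)
  if (!is.null(z)) channels$z <- z
  if (is.null(q)) q <- rep(1, n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  structure(list(grid = grid, dphi = dphi, channels = channels, q = q,
                 valid = valid, units = c(.u = "", z = ""),
                 T_bar = 1, f0 = 1), class = "phase_domain")
}

# minimal cohort container for group-statistics tests:
# h_arr is [subject, response time, phase]
make_group <- function(h_arr, tr, phases, horizon = 3) {
  structure(list(h = h_arr, tr = tr, phases = phases,
                 dt = if (length(tr) > 1) tr[2] - tr[1] else 0.02,
                 horizon = horizon, n = dim(h_arr)[1], T_bar = 1.04,
                 channel = "y", input = "u", units_out = "", units_in = "",
                 fits = NULL),
            class = "phirf_group")
}
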