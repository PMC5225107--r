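# hand-built HTF estimates for inversion tests
synthetic_htf <- function(Hfun_by_mode, k_max = 2, f_max = 62, df = 1 / 40,
                          channel = "z") {
  f1 <- seq(0, f_max, by = df)
  modes <- (-k_max):k_max
  H <- array(0 + 0i, dim = c(length(f1), length(modes), 1),
             dimnames = list(NULL, as.character(modes), channel))
  for (k in modes)
    H[, as.character(k), 1] <- Hfun_by_mode(k, f1)
  structure(list(H = H, f1 = f1, df = df, modes = modes, k_max = k_max,
                 window_cycles = round(1 / df), dphi = 1 / 128, f_max = f_max,
                 outputs = channel, input = ".u",
                 units = c(.u = "", z = ""), T_bar = 1, f0 = 1,
                 n_segments = 1L),
            class = "htf_estimate")
}

test_that("identity and modulated-gain systems invert to phase-domain deltas", {
  # H_0 = 1 on the full band (to Nyquist), no taper: discrete delta at zero
  # lag whose height is the band integral ~ 1/dphi
  htf <- synthetic_htf(function(k, f) if (k == 0) rep(1, length(f)) else 0 * f,
                       f_max = 64)
  ti <- htf_to_irf(htf, channel = "z", phases = (0:9) / 10,
                   taper_frac = 0, mode_taper = 0)
  i0 <- which.min(abs(ti$tau))
  height <- htf$df * (2 * sum(htf$f1 > 0) + 1)        # ~ 1/dphi = 128
  expect_equal(height, 128, tolerance = 1e-3)
  expect_equal(ti$h[i0, ], rep(height, 10), tolerance = 1e-9)
  expect_lt(max(abs(ti$h[-c(i0 - 1, i0, i0 + 1), ])), 128 * 1e-3)

  # modulated gain: H_0 = 1, H_{+-1} = eps -> delta scaled by 1 + 2 eps cos(2 pi phase)
  eps <- 0.1
  htf2 <- synthetic_htf(function(k, f)
    if (k == 0) rep(1, length(f)) else if (abs(k) == 1) rep(eps, length(f)) else 0 * f,
    f_max = 64)
  ti2 <- htf_to_irf(htf2, channel = "z", phases = (0:9) / 10,
                    taper_frac = 0, mode_taper = 0)
  expect_equal(ti2$h[i0, ] / height, 1 + 2 * eps * cos(2 * pi * ti2$phases),
               tolerance = 1e-6)

  # first-order low-pass H_0: one-sided exponential in lag, equal at all phases
  fc <- 2
  htf3 <- synthetic_htf(function(k, f)
    if (k == 0) 1 / (1 + 1i * f / fc) else 0 * f, f_max = 62)
  ti3 <- htf_to_irf(htf3, channel = "z", phases = (0:9) / 10,
                    taper_frac = 0.1, mode_taper = 0)
  sel <- ti3$tau > 0.15 & ti3$tau < 1.5
  ana <- 2 * pi * fc * exp(-2 * pi * fc * ti3$tau[sel])
  expect_lt(sqrt(mean((ti3$h[sel, 1] - ana)^2)) / sqrt(mean(ana^2)), 0.05)
  expect_lt(max(abs(ti3$h[sel, 1] - ti3$h[sel, 7])), 1e-6 * max(ana))

  # conjugate-incomplete mode sets are rejected
  bad <- synthetic_htf(function(k, f) 0 * f)
  bad$modes <- 0:2
  expect_error(htf_to_irf(bad, channel = "z"), "conjugate")
})

test_that("phase impulse response integrates the phase-derivative response", {
  tau <- seq(-1, 4, by = 1 / 128)
  phases <- (0:4) / 5
  mk_tirf <- function(h) structure(
    list(h = h, tau = tau, phases = phases, dtau = 1 / 128, channel = ".q",
         input = ".u", units = c(.u = ""), T_bar = 1, f0 = 1),
    class = "transient_irf")
  # zero in, zero out
  expect_true(all(phase_irf(mk_tirf(matrix(0, length(tau), 5)))$h == 0))
  # delta of area a at onset -> permanent step of height a
  h <- matrix(0, length(tau), 5)
  i0 <- which.min(abs(tau))
  a <- 0.25
  h[i0 + 1, ] <- a / (1 / 128)
  st <- phase_irf(mk_tirf(h))
  expect_equal(st$h[length(tau), ], rep(a, 5), tolerance = 0.01)
  expect_equal(st$h[i0, ], rep(0, 5))
  expect_lt(max(abs(st$h[tau < 0, ])), 1e-12)
  # constant c on (0, L]: ramp to c*L then hold
  h2 <- matrix(0, length(tau), 5)
  h2[tau > 0 & tau <= 0.5, ] <- 3
  st2 <- phase_irf(mk_tirf(h2))
  expect_equal(st2$h[which.min(abs(tau - 0.25)), 1], 3 * 0.25, tolerance = 0.02)
  expect_equal(st2$h[which.min(abs(tau - 2)), 1], 1.5, tolerance = 0.02)
  # sign flag
  expect_equal(phase_irf(mk_tirf(h2), flip_sign = TRUE)$h, -st2$h)
})

test_that("composition reduces correctly in the degenerate cases", {
  ev <- seq(0, 40, by = 1)
  tg <- seq(0, 39.99, by = 1 / 128)
  pm <- approximate_phase(ev, tg, d = 2)
  y <- time_series(cos(2 * pi * tg), 128, units = "deg")
  pds <- to_phase_domain(pm, list(z = y), dphi = 1 / 128)
  cm <- cycle_mean(pds, M = 10)$mean

  tau <- seq(-1, 4, by = 1 / 128)
  phases <- (0:49) / 50
  mk_tirf <- function(vals) structure(
    list(h = vals, tau = tau, phases = phases, dtau = 1 / 128, channel = "z",
         input = ".u", units = c(.u = "", z = "deg"), T_bar = 1, f0 = 1),
    class = "transient_irf")
  hy <- mk_tirf(matrix(rep(exp(-pmax(tau, 0) * 2) * (tau >= 0), 50), ncol = 50))
  zero_theta <- structure(
    list(h = matrix(0, length(tau), 50), tau = tau, phases = phases,
         dtau = 1 / 128, channel = ".q", input = ".u",
         units = c(.u = ""), T_bar = 1, f0 = 1), class = "phase_irf")

  # h_theta = 0: h = f0 * transient part on the time grid
  p1 <- compose_phirf(hy, zero_theta, cm)
  m <- 11                                    # phase 0.20
  lag <- p1$tr - p1$phases[m]
  sel <- lag > 0.05 & lag < 2
  expect_equal(p1$h[sel, m], 1 * exp(-2 * lag[sel]), tolerance = 1e-3)

  # transient = 0, h_theta = unit step: h = y0'(tr) after onset
  hy0 <- mk_tirf(matrix(0, length(tau), 50))
  step_theta <- zero_theta
  step_theta$h <- matrix(as.numeric(tau > 0), length(tau), 50)
  p2 <- compose_phirf(hy0, step_theta, cm)
  sel2 <- which(lag > 0.1)
  expect_equal(p2$h[sel2, m], -2 * pi * sin(2 * pi * p2$tr[sel2]),
               tolerance = 1e-2)
  # baseline attached from the cycle mean
  expect_equal(p2$baseline, cos(2 * pi * (p2$tr %% 1)), tolerance = 1e-3)

  # periodicity h(tr + 1, ts) columns: exact one-cycle shift symmetry
  i_a <- which(abs(p1$tr - 1.2) < 1e-9); i_b <- which(abs(p1$tr - 2.2) < 1e-9)
  m2 <- m                                     # same stimulus phase, lag + 1
  expect_equal(p1$h[i_b, m2], p1$h[i_a, m2] * exp(-2), tolerance = 1e-3)
})

test_that("slicing and restacking preserve the matrix and snap to the grid", {
  mod <- lti_model()
  orc <- oracle_phirf(mod, phases = (0:9) / 10, dt = 0.02)
  s <- slice_phase(orc, 0.281)
  expect_equal(s$phase, 0.3)                 # nearest column on a 0.1 grid
  restack <- vapply(orc$phases, function(p) slice_phase(orc, p)$h,
                    numeric(length(orc$tr)))
  expect_identical(restack, orc$h)
  expect_error(slice_phase(orc, 1.2), "\\[0, 1\\)")
})

test_that("kinematic integration turns velocity responses into position responses", {
  mod <- lti_model()
  orc <- oracle_phirf(mod, phases = (0:9) / 10)
  zero <- orc; zero$h[] <- 0
  expect_true(all(integrate_kinematic(zero)$h == 0))
  # constant c after onset integrates to a ramp c * (tr - ts) seconds
  cst <- orc; cst$h[] <- 0
  for (m in seq_along(cst$phases)) cst$h[cst$tr >= cst$phases[m], m] <- 2
  ik <- integrate_kinematic(cst)
  m <- 4
  lag_s <- (ik$tr - ik$phases[m]) * ik$T_bar
  sel <- lag_s > 0
  expect_equal(ik$h[sel, m], 2 * lag_s[sel], tolerance = 0.05)
  expect_true(all(ik$h[!sel, m] == 0))
})

test_that("the linearized predictor reproduces impulse responses and baselines", {
  mod <- lti_model()
  trials <- lapply(1:3, function(i) sim_visual_trial(mod, seed = 40 + 10 * i,
                                                     scale = 0.3, duration = 150))
  fit <- phirf(trials, response = "y")
  # u = 0 -> baseline only
  dt_s <- fit$dt * fit$T_bar
  u0 <- time_series(numeric(400), 1 / dt_s)
  p0 <- predict(fit, u0)
  expect_equal(p0$values, predict(fit$cycle_mean, (ts_times(p0) / fit$T_bar) %% 1,
                                  channel = "y"), tolerance = 1e-9)
  expect_error(predict(fit, time_series(numeric(5), 1 / dt_s)), "one cycle")
  # impulse of area A at a grid point: deviation = A * h(tr, ts)
  A <- 0.05
  uvec <- numeric(500)
  j <- 151                                   # t_s = 150 * dt_s = 3 cycles
  uvec[j] <- A / dt_s
  ui <- time_series(uvec, 1 / dt_s)
  dev <- predict(fit, ui, type = "deviation", extend_phase = FALSE)
  ts_imp <- (j - 1) * dt_s
  ph_idx <- which.min(abs(fit$phases - (ts_imp / fit$T_bar) %% 1))
  i_on <- which.min(abs(fit$tr - fit$phases[ph_idx]))
  L <- round(fit$horizon / fit$dt)
  got <- dev$values[j:(j + L)]
  want <- A * fit$h[i_on:(i_on + L), ph_idx]
  expect_equal(got, want, tolerance = 1e-8)

  # end-to-end linearity: doubling the perturbation doubles the deviation
  u1 <- trials[[1]]$input
  d1 <- predict(fit, u1, type = "deviation")
  u2 <- u1; u2$values <- 2 * u1$values
  d2 <- predict(fit, u2, type = "deviation")
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-9)
})
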