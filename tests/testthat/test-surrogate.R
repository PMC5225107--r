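test_that("unperturbed noise-free walker is exactly periodic with events 1/f0 apart", {
  mod <- walker_model(phase_sd = 0, trunk_sd = 0)
  mod$process_sd <- 0
  mod$channels$ap_vel$sd <- 0; mod$channels$emg$sd <- 0
  u <- time_series(numeric(120 * 30), 120)
  tr <- simulate_trial(mod, u, seed = 1)
  expect_equal(diff(tr$events), rep(1 / mod$f0, length(tr$events) - 1),
               tolerance = 1e-9)
  y <- tr$channels$trunk$values
  expect_equal(y[1:(120 * 10)], y[1:(120 * 10) + round(120 / mod$f0 * 10)],
               tolerance = 1e-6)
  # channel values follow the baseline harmonics exactly
  expect_equal(y, eval_harmonics(mod$channels$trunk$y0, tr$theta),
               tolerance = 1e-12)
})

test_that("deviations scale linearly with small perturbations", {
  mod <- walker_model(phase_sd = 0, trunk_sd = 0)
  mod$process_sd <- 0
  u1 <- sim_visual_trial(mod, seed = 3, scale = 0.05, duration = 60)
  base <- simulate_trial(mod, time_series(numeric(length(u1$input$values)), 120))
  u2in <- u1$input; u2in$values <- 2 * u2in$values
  u2 <- simulate_trial(mod, u2in)
  d1 <- max(abs(u1$channels$trunk$values - base$channels$trunk$values))
  d2 <- max(abs(u2$channels$trunk$values - base$channels$trunk$values))
  expect_equal(d2 / d1, 2, tolerance = 0.01)
})

test_that("constant-dynamics surrogate matches the classical convolution response", {
  lam <- 3
  mod <- lti_model(lambda = lam)
  tr <- sim_visual_trial(mod, seed = 5, scale = 0.2, duration = 80)
  t <- ts_times(tr$input)
  h <- 1 / 120
  # exact discretization of x' = -lam x + u for piecewise-linear u
  u <- tr$input$values
  a <- exp(-lam * h)
  b0 <- (1 - a) / lam - (h - (1 - a) / lam) / (lam * h)
  b1 <- (h - (1 - a) / lam) / (lam * h)
  x <- numeric(length(u))
  for (k in seq_len(length(u) - 1)) x[k + 1] <- a * x[k] + b0 * u[k] + b1 * u[k + 1]
  base <- eval_harmonics(mod$channels$y$y0, tr$theta)
  dev <- tr$channels$y$values - base
  sel <- which(t > 10 & t < 70)
  expect_lt(sqrt(mean((dev[sel] - x[sel])^2)) / sd(x[sel]), 0.01)
})

test_that("trials and cohorts are reproducible from their seeds", {
  mod <- walker_model()
  u <- differentiate(generate_perturbation(visual_spec_scaled(1, duration = 30), 3))
  a <- simulate_trial(mod, u, seed = 77)
  b <- simulate_trial(mod, u, seed = 77)
  expect_identical(a$channels$trunk$values, b$channels$trunk$values)
  expect_identical(a$events, b$events)
  c1 <- make_cohort(mod, 2, 1, spec = visual_spec_scaled(1, duration = 30), seed = 9)
  c2 <- make_cohort(mod, 2, 1, spec = visual_spec_scaled(1, duration = 30), seed = 9)
  expect_identical(c1[[2]]$trials[[1]]$channels$trunk$values,
                   c2[[2]]$trials[[1]]$channels$trunk$values)
  # zero jitter: all subjects share the generating model
  cz <- make_cohort(mod, 2, 1, spec = visual_spec_scaled(1, duration = 30),
                    seed = 9, jitter = list(f0_sd = 0, amp_sd = 0))
  expect_identical(cz[[1]]$model$f0, cz[[2]]$model$f0)
  # EMG-like channel is nonnegative
  expect_true(all(c1[[1]]$trials[[1]]$channels$emg$values >= 0))
})

test_that("oracle matches analytic responses and converges in pulse area", {
  lam <- 3
  orc <- oracle_phirf(lti_model(lambda = lam), phases = (0:9) / 10)
  expect_true(all(orc$converged))
  for (m in c(2, 7)) {
    lag <- (orc$tr - orc$phases[m]) * orc$T_bar
    sel <- lag >= 0.05 & lag <= 2.5
    ana <- exp(-lam * lag[sel])
    expect_lt(sqrt(mean((orc$h[sel, m] - ana)^2)) / sqrt(mean(ana^2)), 0.01)
    # causality: zero response before the stimulus (allowing the one grid
    # point touched by the two-sample pulse support and interpolation)
    expect_lt(max(abs(orc$h[lag < -0.05, m])), 1e-6)
  }
  # pure phase oscillator: long-time columns follow y0'(tr) * alpha(ts)
  pmod <- phase_oscillator_model()
  orc2 <- oracle_phirf(pmod, phases = (0:9) / 10)
  for (m in c(3, 8)) {
    lag <- orc2$tr - orc2$phases[m]
    sel <- lag >= 1.5 & lag <= 3
    want <- eval_harmonics(pmod$channels$y$y0, orc2$tr[sel] %% 1, deriv = 1) *
      eval_harmonics(pmod$alpha, orc2$phases[m])
    expect_lt(sqrt(mean((orc2$h[sel, m] - want)^2)) / sqrt(mean(want^2)), 0.01)
  }
})

test_that("spring coupling drives the plant with F = k (u - y - u0)", {
  mod <- walker_model(phase_sd = 0, trunk_sd = 0)
  mod$process_sd <- 0
  mod$channels$ap_vel$sd <- 0; mod$channels$emg$sd <- 0
  mod$spring <- list(k = 0.0175, u0 = -40, channel = "trunk")
  u <- time_series(sin(2 * pi * 0.5 * seq(0, 20 - 1 / 120, by = 1 / 120)), 120,
                   units = "cm")
  tr <- simulate_trial(mod, u, seed = 2)
  y <- tr$channels$trunk$values
  expect_equal(tr$force$values, 0.0175 * (u$values - y - (-40)), tolerance = 1e-9)
  expect_true(all(tr$force$values > 0))
  # with k = 0 the plant is unperturbed
  mod0 <- mod; mod0$spring$k <- 0
  tr0 <- simulate_trial(mod0, u, seed = 2)
  expect_equal(diff(tr0$events), rep(1 / mod$f0, length(tr0$events) - 1),
               tolerance = 1e-9)
})

test_that("with no phase modulation the estimated response is flat across phase", {
  mod <- lti_model()
  trials <- lapply(1:4, function(i) sim_visual_trial(mod, seed = 100 + i))
  fit <- phirf(trials, response = "y")
  # peak response per stimulus phase: between-phase SD bounded by the
  # estimation noise floor (acausal region), within a factor of 2
  peaks <- apply(fit$h, 2, max)
  noise <- causality_ratio(fit) * max(abs(fit$h))
  expect_lt(stats::sd(peaks), 2 * max(noise, 1e-12) * 2)
})
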