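# phirf

Phase-dependent impulse response functions for rhythmic movement data.

## The problem

Rhythmic behaviors — treadmill walking is the motivating case — are well
described as noisy limit-cycle oscillators. How such a system responds to a
small perturbation depends on *when* in the cycle the perturbation arrives:
a tug on the trunk at heel strike and the same tug at mid-swing produce
different kinematic and muscular responses. The object that captures this is
the **phase-dependent impulse response function** (ϕIRF), a kernel
`h(t_r, t_s)` giving the change in a response variable at time `t_r` per
unit integral of a perturbation applied at time `t_s`. The perturbed output
is then, to first order,

    y(t_r) = y0(t_r) + ∫ h(t_r, t_s) u(t_s) dt_s

where `y0` is the unperturbed periodic waveform. Probing every stimulus
phase with discrete pulses is experimentally prohibitive; `phirf` instead
estimates the full kernel from *continuous* perturbation recordings, the
experimentally efficient route, and corrects for **phase resetting** — the
permanent phase shifts that make a limit cycle fundamentally different from
a clock-driven (strictly time-periodic) system and that would otherwise
corrupt the estimate.

This package is for movement scientists and computational neuroscientists
doing perturbation-based system identification of gait and other rhythmic
behaviors, and for anyone who wants a self-contained, testable
implementation of the harmonic-transfer-function (HTF) route to ϕIRFs.

## The method in brief

For each trial (perturbation input `u(t)`, outputs `y(t)`, heel-strike
times `t_k`):

1. **Phase estimation.** The event-based phase
   `θ_d(t) = k + f0 (t − t_k)` is smoothed by a causal, critically damped
   second-order filter `θ̈ + 2d(θ̇ − f0) + d²θ = d² θ_d(t)` (rate constant
   `d = 2 s⁻¹`), yielding a continuously differentiable, invertible phase
   `θ(t)`.
2. **Phase warping.** All signals are resampled onto a uniform phase grid:
   `ũ(ϑ) = u(p(ϑ))`, `ỹ(ϑ) = y(p(ϑ))`, plus the phase rate
   `q̃(ϑ) = θ̇(p(ϑ))`, where `p` inverts `θ`.
3. **Cycle mean.** A harmonic fit gives the phase-locked waveform `ỹ0(ϑ)`;
   deviations `ỹ(ϑ) − ỹ0(ϑ)` and `q̃(ϑ) − f0` carry the responses.
4. **Spectra.** Welch power- and *double-frequency* cross-spectral
   densities (40-cycle Hann windows, 50% overlap) give the HTF modes
   `H_k(f1) = p_ũz(f1, f1 + k) / p_ũũ(f1)` coupling input frequency `f1`
   to output frequency `f1 + k` cycles⁻¹, for both the transient and the
   phase-rate channel.
5. **Inversion.** A two-dimensional inverse Fourier transform converts the
   HTFs to phase-domain kernels; the phase-rate kernel is integrated from
   stimulus onset into the phase response `h_θ` (zero at onset, approaching
   the permanent phase shift).
6. **Composition.** The time-domain ϕIRF is
   `h_y(t_r, t_s) = f0 h̃_y(t_r/T̄, t_s/T̄) + ỹ0′(t_r/T̄) h_θ(t_r/T̄, t_s/T̄)`
   — transient response plus the output deviation produced by advancing the
   baseline waveform through the accumulated phase shift.

Group inference uses per-cell normal-theory confidence intervals and
one-sample sign-flip permutation tests with tmax family-wise error control
across all response times within each stimulus phase (α = 0.05, 1000
permutations, 3-cycle horizon).

Everything is validated against a configurable limit-cycle **walker
surrogate** (`walker_model()`, `simulate_trial()`) whose true ϕIRF is
computable by brute-force impulse experiments (`oracle_phirf()`).

## Worked example

Simulate one subject's worth of perturbed walking (six 250-s trials of the
walker surrogate driven by the visual-velocity perturbation), estimate the
trunk ϕIRF, and compare with the brute-force ground truth:

```r
library(phirf)

walker <- walker_model()
cohort <- make_cohort(walker, n_subjects = 1, n_trials = 6, seed = 42,
                      jitter = list(f0_sd = 0, amp_sd = 0))
fit <- phirf(cohort[[1]]$trials, response = "trunk")
summary(fit)
#> phiIRF of trunk to an impulse in .u
#>   grid: 50 stimulus phases, response time 0..4 cycles (step 0.02)
#>   mean cycle period: 1.040 s
#>   peak response 0.9609 deg/(deg/s*s) at stimulus phase 0.18, response time 0.90 cycles
#>   pre-stimulus noise floor: 5.2% of peak

truth <- oracle_phirf(walker, channel = "trunk")
phirf_nrmse(fit, truth)
#> [1] 0.2956             # one subject; pooling more data drives this down

s <- slice_phase(fit, 0.28)
max(s$h); s$tr[which.max(s$h)] - s$phase
#> peak 0.761 deg/(deg/s s), 0.18 cycles after stimulus onset

plot(fit)                # stimulus phase x response time heatmap with onset diagonal
```

The peak response value reads: a brief visual-velocity pulse of unit
integral (1 deg/s · s, i.e. a 1-deg step of scene position) delivered at
stimulus phase 0.18 tips the trunk forward by up to ~0.96 deg about 0.7
cycles later. The pre-stimulus noise floor (response "before" the stimulus,
which must be zero for a causal system) gauges estimation noise.

For a cohort, `phirf_cohort()` fits every subject and
`group_ci()` / `permutation_tmax()` summarize where responses differ
reliably from zero:

```r
g  <- phirf_cohort(make_cohort(walker, 5, 4, seed = 1), response = "trunk")
st <- permutation_tmax(g, n_perm = 1000, seed = 2)
plot(st)                 # significant group-mean responses only
```

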