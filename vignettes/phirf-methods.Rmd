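---
title: "Estimating phase-dependent impulse response functions from continuous perturbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating phase-dependent impulse response functions from continuous perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phirf)
```

## The model class

`phirf` treats a rhythmic behavior as a smooth dynamical system with a
stable limit cycle, observed near that cycle under small continuous
perturbations. Linearizing around the cycle gives a system whose only
nonlinearities are periodic functions of the oscillator's phase: phase
advances at a nominal rate `f0` and can be *reset* by input through a
phase-dependent gain, a transient state decays back to the cycle with
phase-dependent linear dynamics, and each output is a phase-locked baseline
waveform plus a linear read-out of the transient state:

```
theta' = f0 + alpha(theta) u(t)          (+ phase diffusion)
x'     = A(theta) x + B(theta) u(t)      (+ process noise)
y      = y0(theta) + C(theta) x          (+ measurement noise)
```

The object of interest is the phase-dependent impulse response function
(phiIRF) `h(t_r, t_s)`: the change in `y` at time `t_r` per unit integral
of a perturbation at time `t_s`. For a strictly time-periodic (clock-driven)
system the phiIRF is the standard kernel of a linear time-periodic (LTP)
system and could be estimated by harmonic transfer functions (HTFs) alone.
For a limit cycle, input also shifts phase *permanently*: a transient
perturbation produces a non-decaying response (the whole future waveform is
advanced or delayed), which violates the LTP machinery's assumptions. The
estimator here deals with this by tracking phase explicitly and splitting
the response into a transient part and a phase part, recombined at the end.

## The estimation pipeline

Fitting is done by `phirf()`; the steps below name the exported function
implementing each stage.

**1. Causal phase (`stride_stats()`, `approximate_phase()`).** Cycle events
(heel strikes) `t_k` give the mean period `T̄` and `f0 = 1/T̄`, and the
discontinuous phase `theta_d(t) = k + f0 (t - t_k)`. A causal critically
damped second-order filter,

```
theta'' + 2 d (theta' - f0) + d^2 theta = d^2 theta_d(t),   d = 2 s^-1,
```

yields a continuously differentiable phase estimate. The feedforward term
`2 d f0` makes a perfect ramp an exact fixed point, so strictly periodic
gait gives `theta(t) = f0 t` exactly. Causality matters: only events up to
`t` influence `theta(t)`, so the estimate could run online and no
information travels backwards past a perturbation.

**2. Phase warping (`to_phase_domain()`).** With `p` the inverse of
`theta`, all channels are resampled to a uniform phase grid
(`dphi = 1/128` cycle): `u~(phase) = u(p(phase))`, likewise the outputs,
plus the phase rate `q~(phase) = theta'(p(phase))`. In this time base the
system's period is exactly one cycle regardless of tempo fluctuations.

**3. Cycle mean (`cycle_mean()`).** The phase-locked waveform `y0~` is a
least-squares harmonic fit of order `M = 20`, which both averages and gives
an exact analytic derivative `y0~'` needed in step 6. Harmonic regression
was chosen over phase-bin averaging precisely because the composition step
needs a smooth derivative; with 128 samples per cycle an order-20 fit
reproduces any band-limited waveform a gait channel can carry. The
phase-rate deviation is `q~ - f0` with the scalar `f0`, not a fitted mean.

**4. Spectra (`welch_psd_csd()`, `pool_spectra()`, `compute_htf()`).**
Welch estimates with 40-cycle Hann windows aligned to integer phases and
50% overlap give the input PSD and the double-frequency CSDs
`p_uz(f1, f1 + k)`; mode `k` couples input frequency `f1` to output
frequency `f1 + k` (in cycles^-1 the harmonic spacing is exactly one, i.e.
`k * window_cycles` FFT bins). HTF modes are `H_k(f1) = p_uz / p_uu` on the
band `(0, 10]` cycles^-1, `k` in `-10..10`. Windows containing any invalid
sample (ramps, slack-spring intervals) are skipped, not zero-filled.
Spectra are pooled across trials with segment-count weights.

**5. Inversion (`htf_to_irf()`, `phase_irf()`).** Each mode's band-limited
inverse transform `g_k(tau)` is assembled as
`h(phase_r, phase_s) = Re sum_k g_k(phase_r - phase_s) e^{i 2 pi k phase_r}`,
with negative input frequencies filled by conjugate symmetry
(`H_{-k}(-f) = conj(H_k(f))`), so the kernel is real by construction. The
phase-rate kernel is integrated over response phase from stimulus onset,
giving `h_theta` with `h_theta(phase_s, phase_s) = 0`; a transient
phase-rate response integrates to the permanent phase shift it causes.

**6. Composition (`compose_phirf()`).** On the output grid (50 stimulus
phases x response times 0..4 cycles in 0.02-cycle steps),

```
h_y(t_r, t_s) = f0 h~_y(t_r/T̄, t_s/T̄) + y0~'(t_r/T̄) h_theta(t_r/T̄, t_s/T̄).
```

The two terms are complementary: immediately after a stimulus the causal
phase estimate still lags the true phase, so the response appears in the
transient channel; as the estimate converges (via subsequent events and the
filter), the response migrates into the phase term. Their sum is the full
kernel at every lag. Periodicity `h(t_r + T̄, t_s + T̄) = h(t_r, t_s)` holds
exactly by construction; causality is *reported* (the pre-stimulus region
is kept as a noise-floor diagnostic, `causality_ratio()`), not enforced,
though an `enforce_causality` flag exists.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `d` | 2 | 1/s | phase-filter rate constant; smaller = smoother, laggier phase |
| `dphi` | 1/128 | cycle | phase grid step; power of two for FFT-sized windows |
| `M` | 20 | – | cycle-mean harmonic order |
| `window_cycles` | 40 | cycles | Welch window; sets frequency resolution 1/40 cycle^-1 |
| `overlap` | 0.5 | – | Welch overlap |
| `k_max` | 10 | modes | HTF modes retained; top 2 tapered to zero |
| `f_max` | 10 | cycle^-1 | analysis band top; Hann edge taper over the top 20% |
| `n_phases`, `dt`, `horizon` | 50, 0.02, 3 | – / cycle / cycles | output grid |
| `alpha`, `n_perm` | 0.05, 1000 | – | statistics defaults |

## Numerical choices

- **Phase filter discretization.** The filter state `[theta, theta']` is
  advanced by an exact first-order-hold discretization, in closed form for
  the critically damped system (double pole at `-d`). Because `theta_d` is
  piecewise linear between events, this reproduces ramp tracking to machine
  precision, which a zero-order hold would miss by O(step).
- **Interpolation.** Phase inversion and channel resampling use monotone
  (Fritsch–Carlson) piecewise-cubic interpolation: monotonicity of
  `p(phase)` is preserved and there is no overshoot at events. The oracle
  resamples impulse-response differences with the same local interpolant so
  its pre-stimulus region stays exactly zero.
- **Per-segment mean removal in Welch.** Each windowed segment has its
  sample mean removed before tapering. The phase-rate deviation has a small
  positive mean (of order `var(theta')/f0`) and segment means fluctuate;
  the Hann window maps a constant exactly onto FFT bins 0 and ±1, so
  without this step the lowest analysis frequencies — which carry the
  permanent phase-shift content — acquire large spurious components that
  integrate into ramps in `h_theta`. The DC bin itself is excluded from the
  band and filled by constant extrapolation from the first band bin.
- **Band and mode tapers.** A Hann edge taper over the top 20% of the band
  and a linear taper over the top two modes control Gibbs ringing from the
  finite band. The estimator's lag resolution is therefore band-limited;
  comparisons against analytic kernels with onset discontinuities are made
  through the identical band limit.
- **Step-5 integration orientation.** `h_theta` accumulates *forward* from
  stimulus onset (zero at onset), which is the orientation required for the
  composition formula to reproduce brute-force impulse experiments; the
  opposite orientation is available via `flip_phase_sign` for sensitivity
  checks.
- **Group delay.** Acquisition delays (e.g. 48 ms for wireless EMG) are
  corrected by the nearest integer sample shift with the sub-sample
  residual reported as an attribute.
- **Degenerate inputs.** Zero-variance cells are excluded from the tmax
  family and given p = 1; coincident markers invalidate samples rather than
  erroring the whole trial; invalid-gap boundaries use one-sided
  differences.

## The walker surrogate and what the tests show

`walker_model()` emulates treadmill-walking data: `f0 = 1/1.04` Hz; a
trunk-orientation-like channel (degrees, baseline dominated by the second
stride harmonic, ~1.7 deg amplitude), an A-P-velocity-like channel and a
nonnegative EMG-envelope-like channel; phase-modulated transient dynamics
(time-average pole -3 s^-1); a phase-response gain
`alpha(theta) = 0.02 + 0.016 sin(2 pi theta)` cycles per (deg/s · s);
phase diffusion giving ~1% stride-time CV; 0.1 deg kinematic measurement
noise. Trials are driven by the derivative of the generated visual-scene
signal (the velocity convention for visual perturbations), 250 s long with
the first and last 5 s masked. Integration is fixed-step RK4 at 120
samples/s with per-step Gaussian noise increments; cohorts add optional
per-subject jitter of `f0` (SD 0.04 Hz) and of waveform/gain amplitudes
(10% relative).

`oracle_phirf()` computes ground truth by brute force: noise-free paired
simulations with and without a small input pulse at each stimulus phase,
divided by the pulse area, with a convergence check that halves the pulse
area and flags columns changing by more than 1%.

The validation suite checks, among others: closed-form recovery of a
memoryless phase-modulated gain (`H_0 = 1`, `H_{±1} = 0.1`) and of a
first-order low-pass transfer function; recovery of the walker oracle by a
5-subject × 4-trial cohort (normalized RMSE < 0.3, with error decreasing
as data volume grows); capture of the phase-resetting signature
`y0~'(t_r) alpha(t_s)` on a pure phase oscillator; FWER calibration of the
tmax test at 5% over 1000 Gaussian-null replicates (20 subjects, 151-cell
families) and 95% CI coverage; and held-out trial prediction R² ≥ 0.9 for
a noise-free plant. These problem sizes were chosen to exercise the
estimator at realistic single-lab data volumes while keeping the suite
quick to run.

What passing these tests does *not* show about real data: the surrogate's
phase dependence is low-order harmonic and its noise is Gaussian and
white; real gait has richer harmonic structure, non-stationarity (fatigue,
adaptation), heel-strike detection errors (an optional event-jitter hook
exists), soft-tissue artifact that is neither white nor phase-independent,
and EMG whose amplitude statistics are signal-dependent. The surrogate
validates the estimator's mathematics, not the biological interpretation
of any particular dataset.

## The linearization and its limits

The phiIRF is a small-signal object. Two practical consequences showed up
clearly during validation and are worth knowing:

- **Finite perturbations bias phase-locked structure.** Continuous
  deployed-scale perturbations make the oscillator's phase jitter around
  the estimate; phase-locked quantities are effectively smeared by that
  jitter, attenuating high harmonics, and second-order terms leak into the
  linear estimate. With the walker's gain settings, the deployed visual
  signal adds a systematic component of roughly 0.1 normalized RMSE to
  long-lag kernel recovery; probes at ~10% of deployed amplitude remove
  it. The linear-regime checks in the test suite therefore use small
  probes, mirroring the oracle's pulse-area convergence requirement, while
  the end-to-end cohort check runs at deployed scale, where the extra
  component is small relative to its error budget.
- **Prediction horizon and phase accumulation.** With phase-dependent
  resetting, accumulated phase shifts random-walk without bound, so over
  minutes a trajectory leaves the linear regime no matter how good the
  kernel is. `predict.phirf()` carries contributions older than the kernel
  horizon through a running phase-shift accumulator built from the
  kernel's limiting phase response (`extend_phase = TRUE`, the default);
  without it, truncating Eq. 1 at the horizon discards the permanent part
  of old responses and predictions of resetting systems fail badly.

Other known limitations: phase information enters only once per cycle
(through events), so the phase-dependent structure of resetting is
band-limited by the event rate and the filter constant `d`; estimator
variance grows with the number of retained modes (error energy roughly
proportional to `k_max / n_segments`), so short recordings favor smaller
`k_max`; and confidence bands for the HTF itself (coherence-based) are not
implemented.

## Data interfaces

Trials are plain lists (`input`, `channels`, `events`) of `time_series`
objects; `write_cohort()` / `load_dataset()` round-trip a cohort through a
plain-text layout (CSV channel tables, single-column event files, YAML
manifest with exclusion intervals applied as validity masks).
`export_phirf()` writes kernels and statistics as long-format CSV;
`plot()` methods render the stimulus-phase × response-time heatmaps with
the onset diagonal.
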