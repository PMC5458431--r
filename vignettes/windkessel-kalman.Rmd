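---
title: "Model-based denoising of aortic pressure waveforms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based denoising of aortic pressure waveforms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abpkalman)
```

## The model and its assumptions

The package treats aortic circulation as a four-element Windkessel: the
arterial tree lumped into characteristic aortic impedance $r$ in series
with the parallel combination of arterial compliance $C$, peripheral
resistance $R$ and blood inertance $L$. The state is $x = (v_C, i_L)$,
the compliance pressure (mmHg) and inertance flow (ml/s); the aortic flow
$i(t)$ (ml/s) is the known input and the aortic pressure $v(t)$ (mmHg)
the output:

$$\frac{dv_C}{dt} = \frac{i}{C} - \frac{v_C}{RC}, \qquad
  \frac{di_L}{dt} = \frac{r}{L}\,(i - i_L), \qquad
  v = r\,(i - i_L) + v_C.$$

The modelling assumptions that matter:

* **Static, linear parameters.** $R, C, r, L$ are constants over a run.
  Real vasculature is nonlinear and time-varying (vasomotor tone,
  respiration); the Kalman gain partially compensates for parameter
  mismatch by blending in measurements, which is precisely why the
  steady-state gain is a diagnostic of model quality.
* **Known, noise-free flow input.** The filter treats $u(k)$ as exact.
  Flow-probe noise is not modelled; it would enter as additional process
  noise.
* **Additive, white, Gaussian, stationary noise** on the pressure channel
  with constant covariances. Spikes violate this; the filter still
  attenuates them but is not optimal for them.

Euler-forward discretization at period $T_s$ gives
$A = \mathrm{diag}(1 - T_s/RC,\; 1 - T_s r/L)$,
$B = (T_s/C,\; T_s r/L)$, $H = (1, -r)$, feedthrough $D = r$. $A$ is
diagonal: the two states couple only through the shared input. The step
is stable iff $T_s < 2RC$ and $T_s < 2L/r$; with the shipped constants
the binding constraint is $2L/r \approx 0.112$ s, comfortably above the
2 ms step of 500 Hz sampling, where both diagonal entries of $A$ lie in
$(0.96, 1)$. `wk_discretize()` computes the stability flag, warns on
violation, and `wk_simulate()` refuses unstable models unless overridden.

## The filter

A standard discrete linear Kalman filter runs on this model, with one
structural choice worth stating: the measurement innovation is
$z(k) - H\hat x^-(k) - D\,u(k)$, i.e. it includes the feedthrough term
$r\,u(k)$ of the output equation. The textbook measurement equation
$z = Hx + v$ has no feedthrough, but the Windkessel output does; omitting
the term would bias every innovation by $r\,u(k)$ (up to
$0.105 \times 314 \approx 33$ mmHg at peak ejection). The covariance
update uses the simple form $(I - KH)P^-$ with post-hoc symmetrization;
the Joseph form is available via `joseph = TRUE`, and the test suite
checks both agree at the optimal gain.

### Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| $R$ | mmHg/(ml/s) | 1.72 | published systemic-circulation estimate (pig) |
| $C$ | ml/mmHg | 0.48 | same source |
| $r$ | mmHg/(ml/s) | 0.105 | same source; $r=0$ admitted as degenerate case |
| $L$ | mmHg/(ml/s²) | 0.0059 | same source |
| $T_s$ | s | 0.002 | 500 Hz, the sampling rate of the emulated recordings |
| $Q_{proc}$ | state units² | diag(1.58, 0.01) | calibrated, see below |
| $R_{meas}$ | mmHg² | 25 | $(5\ \mathrm{mmHg})^2$, matching the default artifact sigma |
| $P(0)$ | — | diag(1000) | weakly informative: early measurements dominate |
| $\hat x(0)$ | — | $(z_1, 0)$ | first measured pressure; reduces the initial transient |

**Calibration of the noise covariances.** No published values exist for
$Q_{proc}$ and $R_{meas}$ in this setting; only the steady-state gain
constrains them. $R_{meas} = 25$ was fixed first from the nominal 5 mmHg
measurement-noise level. The $v_C$ entry of $Q_{proc}$ was then chosen
once, by solving the steady-state Riccati equation for the shipped model
at 500 Hz, so that the $v_C$ component of the steady-state gain equals
0.22 — the regime in which the model is trusted roughly 4:1 over the
measurements — giving 1.58 (the exact root is 1.5779; the shipped value
is rounded to two decimals and yields a gain of 0.2201). The $i_L$ entry
is set small (0.01) since that state is only weakly observable through
$H = (1, -r)$. These are calibrated package defaults, not published
physiologic constants, and are marked as such in the shipped config.
Raising $R_{meas}$ (or lowering $Q_{proc}$) monotonically lowers the
gain, i.e. shifts trust toward the model; the suite asserts this
monotonicity.

`steady_state_gain()` iterates the covariance recursion from $P = 0$
until the a priori covariance changes by less than `tol` (default
1e-12); for the shipped configuration this takes a few hundred
iterations, and the time-varying gain of `run_kalman()` matches the
fixed point at late samples.

## The synthetic-data generator

No recordings ship with the package, so `make_dataset()` emulates the
study conditions end to end:

* **Flow**: each beat is a half-sine ejection pulse of duration
  `systolic_fraction × period` followed by zero diastolic flow. The
  half-sine is an analytically integrable stand-in for a measured
  ejection profile: its continuous-time peak is $SV\,\pi/(2 t_{sys})$,
  and the sampled pulse is rescaled by the ratio of the continuous to the
  discrete (Riemann-sum) integral — a correction of order $10^{-5}$ at
  500 Hz — so every beat ejects exactly the stroke volume. Defaults
  (60 bpm, 70 ml, fraction 0.35, 500 Hz, 10 s) put the cardiac
  fundamental at exactly 1 Hz and mean flow at a physiologic 70 ml/s.
  The heart period must tile the sample grid (checked to 0.01 sample) so
  beats are sample-identical.
* **Clean pressure**: open-loop Euler simulation of the discretized
  model, started at the DC operating point
  ($v_C = R\,\bar i,\ i_L = \bar i$) and with the first 5 cardiac periods
  discarded, so the retained waveform is at periodic steady state (the
  suite checks period-to-period agreement to $10^{-3}$ of the pressure
  amplitude).
* **Corruption**: additive zero-mean Gaussian noise (default
  $\sigma = 5$ mmHg) on every sample plus optional spikes, optionally
  confined to an artifact window — mimicking records in which artifacts
  concentrate in a known interval. Corruption is evaluated under a local
  RNG seed, so a fixed seed reproduces the dataset bit-exactly without
  disturbing the caller's RNG stream, and the bundle's metadata record
  regenerates it from scratch.

What the generator does **not** emulate: measured ejection morphology
(dicrotic notch on the input side), beat-to-beat variability,
respiratory modulation, baseline wander, damping/blockage artifacts, and
flow-channel noise. Passing tests therefore demonstrate correctness of
the mechanics and the filter's behavior under the stated noise model —
not performance on real catheter recordings.

## Spectral validation

`power_spectrum()` is a plain periodogram (squared DFT magnitude,
rectangular window by default, Hann optional), folded to $0..f_s/2$ and
normalized so the bin powers sum to the mean square of the input
(Parseval, asserted to $10^{-6}$ relative). The simplest estimator
suffices because the validation criterion is peak *location*, not
magnitude: a physiological ABP waveform shows a harmonic at the cardiac
fundamental (the forward ejection wave) and one at twice it (the
reflected wave from arterial bifurcations), with the DC bin excluded as
it only encodes mean pressure. `harmonic_peaks()` returns the largest
local maxima above a 0.25 Hz floor; the matching tolerance for the
"≈1 Hz / ≈2 Hz" checks is one frequency bin or ±0.1 Hz, whichever is
larger (at the default 10 s record both equal 0.1 Hz). Peak locations
are invariant to amplitude scaling, which the suite asserts.

`estimation_error()` operationalizes "error does not accumulate" as the
ratio of mean absolute error over the last 0.25 s to the first 0.25 s of
a 2 s analysis window (≤ 2 passes); `snr_improvement()` scores denoising
as $10\log_{10}$ of the error-power ratio before/after, against the clean
reference the generator provides.

## Numerical and design choices

* **State order** is fixed as $(v_C, i_L)$ so the output matrix is
  $H = (1, -r)$ with the measured (pressure) state first.
* **Euler forward, not exact discretization**, is the production path —
  it is the model formulation being studied, not merely an integrator. A
  fine-step RK4 integrator exists in the test helpers as an independent
  oracle; the suite verifies the Euler trajectory converges to it as
  $T_s$ shrinks (first-order behavior).
* **Degenerate case $r = 0$**: the output reduces to $v_C$, the $i_L$
  state is frozen ($A_{22} = 1$), unforced and unobserved; this marginal
  entry is deliberately not flagged unstable since the state is bounded
  and inert.
* **Tie-breaks in the peak finder**: a local maximum must be strictly
  above its left neighbor and at least its right neighbor, so a plateau
  yields its leftmost bin; requested-but-missing peaks are returned short
  with an `incomplete` flag rather than an error.
* **Covariances are symmetrized** after every update, and the constructor
  rejects asymmetric or indefinite $Q_{proc}$ (eigenvalue floor
  $-10^{-10}$).
* **I/O precision**: waveform CSVs carry 17 significant digits, making
  the write/read round trip bit-exact; the reader rejects NaN samples
  (naming the row) and time columns that deviate from the uniform grid by
  more than 1 µs.
* **Problem sizes**: the default record is 10 s (5000 samples); tests use
  1–20 s records and a 20-seed noise sweep, which keeps the full suite in
  the tens of seconds while leaving every assertion at its stated
  tolerance.

## Known limitations

* The filter is causal; no fixed-interval (RTS) smoothing is provided.
* Constant $Q$/$R$: no adaptive noise estimation or signal-quality
  weighting. Spike artifacts are attenuated, not rejected.
* Two-element and three-element Windkessel variants, time-varying or
  subject-fitted parameters, and hemodynamic parameter estimation
  (CO/SV) are out of scope.
* The noise covariances are calibrated to a single operating point (the
  shipped model at 500 Hz); a different sampling rate or parameter set
  warrants recalibration against the same steady-state-gain criterion.
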