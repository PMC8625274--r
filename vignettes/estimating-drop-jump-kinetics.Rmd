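---
title: "Estimating drop-jump kinetics from inertial sensors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating drop-jump kinetics from inertial sensors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjkinetics)
```

## The estimation problem

The vertical drop jump (VDJ) is a standard plyometric screening task: the
athlete steps off a 30 cm box, lands, and immediately performs a maximal
vertical jump. The biomechanical quantities of interest during the *first
landing phase* — the three-dimensional ground reaction force (GRF) and the
knee flexion/extension (FE), adduction/abduction (AA) and internal/external
rotation (R) moments — normally require a force plate and an optical motion
capture system feeding an inverse-dynamics model. `vdjkinetics` implements
a laboratory-free alternative: three body-worn inertial measurement units
(sacrum, right thigh, right shank; 3-axis accelerometer ± gyroscope at
128 Hz) drive a NARX recurrent network that regresses the six kinetic
targets sample by sample.

The package covers the complete workflow needed to *train and validate*
such a model:

1. **Signal infrastructure** (`sampled_signal`): a uniform-rate,
   multi-channel container with zero-phase Butterworth filtering,
   band-limited rational resampling, gravity removal and frame cropping.
   All frame windows are half-open and 0-based; each stream carries `t0_s`,
   its start time on a shared trial clock.
2. **Synchronization**: the optical and inertial systems free-run on
   separate clocks. Each session starts with an operator shaking the master
   sensor (with an attached reflective marker) for five or more ~1 Hz
   cycles; `sync_streams()` resamples the marker trajectory to 128 Hz,
   gravity-removes and low-pass filters (4th order, 10 Hz) the master
   vertical acceleration, auto-detects the spike window on both streams,
   and estimates the clock offset by normalized cross-correlation.
3. **Segmentation**: contacts are detected on the *unfiltered* summed
   vertical GRF against a 10 N threshold; each drop jump produces a pair of
   contacts of which the first (touch-down to take-off) is the analysis
   window.
4. **Dataset assembly**: per landing, a 25-column block — a per-jump frame
   index, 18 IMU predictor channels filtered at 32 Hz (12 and 24 Hz
   variants available), and six targets with the GRFs normalized by body
   mass (N/kg).
5. **NARX model**: `y(t) = f(y(t-1), y(t-2), u(t-1), u(t-2))` with a
   layered fully connected `f`, trained open-loop (series–parallel: the
   *measured* past targets fill the feedback delay line) with resilient
   backpropagation on a regularized MSE.
6. **Evaluation**: repeated random subject-level 7/4 train/test splits,
   per-target pooled RMSE summarized as mean/max/min across folds, and
   20-bin train/test error histograms.

## The synthetic cohort

Real recordings of this protocol are not required for development or
validation: `simulate_cohort()` generates complete sessions with known
ground truth. The generator's defaults *are* the study conditions: 11
subjects, up to 10 jumps each, body mass uniform on 50–85 kg, first-landing
contact durations uniform on 0.25–0.45 s, integer clock offsets on ±500
frames at 128 Hz, and a five-cycle 1 Hz synchronization shake.

Internally every session is a set of continuous-time channel models sampled
at each device's rate, which keeps all modalities mutually consistent to
machine precision before noise:

* Each generic IMU channel is a sum of slow sinusoidal "body sway"
  processes plus a smooth two/three-lobe landing transient per jump
  (gyroscopes ~100–350 °/s, accelerometers ~5–25 m/s²; vertical
  accelerometer channels carry a +9.81 m/s² gravity offset).
* The total vertical GRF is a strictly positive two-peak pulse peaking at
  2–4 body weights, with a smoothstep onset fast enough that the 10 N
  crossing is unambiguous (slope ≈ 60 N per 200 Hz frame) yet band-limited
  well below the 32 Hz IMU filter. The sacrum vertical accelerometer
  carries this pulse divided by body mass — the synthetic counterpart of
  Newton's second law — so the vertical GRF target is exactly recoverable
  from the sensed data.
* The remaining five targets are produced by a fixed known mapping
  `y_j(t) = Σ_s W1[j,s]·tanh(α·u_s(t-1)) + W2[j,s]·u_s(t-2) + c_j`
  using only delays 1 and 2, so the default NARX delay set is
  well-specified. The gain α = 0.002 keeps the tanh branch mildly
  nonlinear over the simulated sensor ranges. A `misspecify` switch adds a
  small delay-3 term for robustness studies.
* Noise is added only after all ground-truth bookkeeping: IMU channels
  0.02 sensor units, knee-moment streams σ = 0.05 N·m/kg (standing in for
  inverse-dynamics model error), force plates 1 N per channel (a typical
  laboratory plate noise floor — deliberately far below the 10 N contact
  threshold so unloaded plates do not chatter across it).

What the simulator does **not** emulate: musculoskeletal dynamics, soft
tissue artefacts, sensor drift or clock skew (the offset is a single
constant per session, as in the measurement protocol), marker occlusion,
and between-foot load asymmetry. Passing the end-to-end tests therefore
demonstrates that the *pipeline machinery* — synchronization, cutting,
normalization, regressor preparation, training, subject-wise evaluation —
is correct and leak-free, not that the network would reach any particular
accuracy on real athletes.

## Numerical and design choices

**Zero-phase filtering.** The published protocol does not say whether its
Butterworth filters were applied causally. Filtering here is
forward–backward by default: all filtering is offline and a phase lag would
bias the cross-correlation delay estimate. Single-pass mode is retained
(`zero_phase = FALSE`); its gain at the cutoff is the analytic −3 dB point,
which the test suite verifies against the closed form
`|H(f)| = (1 + (f/fc)^(2·order))^(-1/2)`.

**Band-limited resampling.** The 100 Hz marker stream must reach the
128 Hz working rate (a 32/25 ratio). Linear interpolation would smear
landing transients, so resampling is polyphase: zero-stuffing, a
windowed-sinc low-pass at the tighter Nyquist, group-delay compensation and
decimation, with reflective padding at the edges. A round trip
128 → 100 → 128 Hz reproduces band-limited content within 1% RMS.

**Spike-window auto-detection.** The published workflow cut the trigger
windows manually. `find_spike_window()` automates this: band-pass to
0.5–3 Hz, moving-RMS envelope, then the *earliest* sufficiently long run
above a descending threshold grid that stands clearly above the quiet
background. The position prior matters: later jump landings can carry more
band energy than the hand shake, but the shake always comes first. A manual
window override is accepted for parity with the original procedure, and a
failed detection falls back to whole-record correlation with a flag.

**Lag bookkeeping.** `estimate_delay()` works on crops but accounts for
their `t0_s`, so the returned lag is always the offset between the full
streams' clocks; alignment (`t0_s ← t0_s − lag_s`) never touches sample
values and re-estimation after alignment returns zero. Lags are integer
frames at 128 Hz; no sub-frame refinement is attempted because the
protocol reports none.

**Contact detection.** Entry is strict `> 10 N` on the unfiltered summed
vertical GRF, exit at `≤ 10 N`. Two decisions close gaps the 10 N rule
leaves open: contacts shorter than 0.1 s are discarded *before* contacts
separated by less than 0.05 s of unloaded time are merged (debounce first,
so isolated noise blips cannot be glued onto a genuine onset), and window
edges are kept only if loading reaches twice the threshold within one
frame (`confirm_factor = 2`). Without that confirmation margin, two
consecutive noise frames adjacent to an onset (probability ≈ 5·10⁻⁴ per
boundary at 5 N RMS noise) would widen the window by two frames; with it,
boundaries stay within ±1 frame at realistic onset slopes.

**Cross-rate window mapping** rounds the start down and the end up, so a
landing is never clipped when moving between the 200 Hz plate clock and
the 128 Hz working rate.

**Regressor isolation.** Delay lines never cross a jump boundary: each
landing of length L contributes L − 2 regressor rows filled entirely from
within that landing. Concatenating jumps into one table and letting delays
straddle the seam would mix unrelated time points.

**Training.** Full-batch resilient backpropagation (iRprop⁻ update rule)
on `perf = γ·MSE + (1−γ)·MSW` with γ = 0.5, Δ₀ = 0.07, Δmax = 50,
η⁺ = 1.2, η⁻ = 0.5; training always runs to the configured last epoch, and
the whole weight trajectory is reproducible from the seed. Weight
initialization is uniform ±1/√fan-in from a private RNG stream.

**Input scaling.** The regressors mix units spanning four orders of
magnitude (frame indices, °/s, m/s², N/kg), and the delayed copies
`u(t-1)`/`u(t-2)` of smooth 128 Hz signals are ~0.99 correlated. Because
Rprop uses only gradient *signs* with per-weight step sizes, that
near-collinearity creates a stiff valley it traverses very slowly. The
default preprocessing therefore whitens the regressors (centre, then
rotate/scale to unit covariance via SVD, with a floored spectrum so exactly
collinear directions — such as the two delayed frame-index columns — map to
zero instead of amplified noise). The transform is fitted on the training
side only and frozen into the model artifact. Per-column z-scoring
(`"zscore"`) and raw scales (`"none"`) remain available; target columns are
never rescaled, since the wide-range vertical GRF would otherwise be
down-weighted in the shared loss. Reference implementations of this network
family apply an analogous min-max input normalization by default.

**Evaluation.** "20-fold cross-validation" over 11 subjects is read as 20
*repeated random* 7/4 subject splits (11 subjects admit no 20-part
partition); fold *i* uses seed `base_seed + i − 1` for both the split and
the weight initialization. Test RMSE pools all test rows per target; the
fold summary reports mean/max/min per target across folds. Histograms use
20 uniform bins over the pooled train+test error range with the zero-error
position reported.

## Problem sizes used in the tests

The full-scale topology (two hidden layers of 1000 linear units, 5000
epochs) is configurable but deliberately not exercised by the test suite.
Validation uses a reduced network — hidden layers `[32, 32]`, 300 epochs,
3 folds — on the default 11 × 10 cohort (~4900 landing-phase rows), which
is where the package's recovery claims are calibrated: held-out per-target
RMSE reaches the generator's noise floor (≈ σ for the moment targets,
below it for the GRF targets, whose plate-noise floor is lower), well
within 1.5 σ. Unit tests use still smaller linear ARX cohorts where the
exact optimum is available in closed form from least squares.

## Known limitations

* Events still come from the force plates; no IMU-only event detection is
  attempted.
* Only the right knee and right-plate GRFs are modelled; no left-limb
  estimation.
* The closed-loop (parallel) rollout is provided for completeness but is
  not trained against; the workflow trains and evaluates open-loop.
* No clock-drift modelling; a single constant offset per session.
* Sensor orientation (quaternions) is intentionally not an input.
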