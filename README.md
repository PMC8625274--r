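# vdjkinetics

Estimation of three-dimensional ground reaction forces (GRFs) and knee
joint moments during the first landing phase of a Vertical Drop Jump
(VDJ), from three body-worn inertial measurement units — sacrum, right
thigh and right shank — instead of a force plate and an optical
inverse-dynamics pipeline. The package is aimed at movement scientists and
sports biomechanists who want a laboratory-free estimate of landing
kinetics for screening and training-load monitoring, and at anyone who
needs a fully testable reference implementation of the underlying
workflow.

## The model

The six kinetic targets `y(t)` — knee flexion/extension, adduction/
abduction and rotation moments (N·m/kg) and the three GRF components
(N/kg) — are regressed sample-by-sample at 128 Hz by a NARX network
(nonlinear autoregressive with exogenous input):

    y(t) = f( y(t-1), y(t-2), u(t-1), u(t-2) )

where `u(t)` are the 19 predictors (a per-jump frame index plus 18 IMU
channels) and `f` is a fully connected layered network. Training and
evaluation run in series–parallel (open-loop) mode: the *measured* past
targets fill the feedback delay line, so `f` is a pure feedforward map of
the prepared regressors. The network is trained full-batch with resilient
backpropagation (Rprop) on a regularized objective
`γ·MSE + (1−γ)·MSW` (γ = 0.5, MSW = mean squared weight), and scored with
the per-target root mean square error

    RMSE = sqrt( Σ_i (ŷ_i − y_i)² / n )

pooled over all test samples, under repeated random subject-level 7/4
train/test splits so no subject's jumps ever appear on both sides.

Around the model, the package implements the complete workflow: a
uniform-rate signal container with zero-phase Butterworth filtering and
band-limited 100→128 Hz resampling; cross-correlation synchronization of
the optical and inertial clocks from the quasi-periodic hand-shake trigger
recorded at the start of each session; first-landing segmentation on the
unfiltered vertical GRF against a 10 N threshold; assembly of the
canonical 25-column training table (with 12/24/32 Hz IMU filter variants
and body-mass-normalized GRFs); cross-validated evaluation with 20-bin
error histograms; and a synthetic drop-jump cohort generator with known
ground truth (clock offsets, contact windows, and an exactly known
IMU-to-kinetics mapping) that makes the whole pipeline testable without
any recorded data.

## Worked example

Simulate the default cohort (11 subjects × 10 jumps), synchronize one
session, build the training table, and cross-validate a reduced network
(runs in about a minute):

```r
library(vdjkinetics)

spec   <- cohort_spec(seed = 42)
cohort <- simulate_cohort(spec)

# synchronize the optical marker and the sacrum vertical accelerometer
session <- cohort$sessions[[1]]
sync_streams(session$marker, signal_channel(session$imu$sa, "acc_z"))
#> <sync_result> lag = 240 frames (1.8750 s) @ 128 Hz, peak r = 0.9999
session$truth$offset_frames
#> [1] 240

# full pipeline: sync -> segment -> cut -> 25-column table
ds <- assemble_datasets(cohort$sessions, default_config())[["32"]]
dim(ds)   # 4898 rows x 27 cols (25 canonical + subject/jump bookkeeping)

# subject-wise cross-validation of a reduced network
cfg    <- narx_config(hidden_sizes = c(32, 32), epochs = 300)
report <- cross_validate(ds, cfg, n_folds = 3, n_train = 7, base_seed = 1)
report
#> <evaluation_report> 3 fold(s), 7 train subjects per fold
#> test RMSE across folds (mean / max / min):
#>   knee_fe  0.0501 / 0.0507 / 0.0494 N·m/kg
#>   knee_aa  0.0513 / 0.0515 / 0.0511 N·m/kg
#>   knee_r   0.0504 / 0.0510 / 0.0498 N·m/kg
#>   grf_x    0.0126 / 0.0138 / 0.0118 N/kg
#>   grf_y    0.0130 / 0.0142 / 0.0119 N/kg
#>   grf_z    0.0229 / 0.0233 / 0.0224 N/kg
```

The estimated clock offset matches the generator's drawn offset exactly,
and the held-out RMSE sits at the generator's noise floor: the moment
targets carry σ = 0.05 N·m/kg of injected noise and are recovered at
≈ 0.050; the GRF targets, whose force-plate noise floor is lower, are
recovered below it. `plot_error_histograms(report)` draws the two-panel
20-bin train/test error histogram with the zero-error marker.

A thin command-line wrapper over the same functions is installed as
`exec/vdjkinetics` (subcommands `simulate`, `sync`, `segment`, `train`,
`predict`, `crossval`, `run`), configured by a YAML file understood by
`load_config()`.

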