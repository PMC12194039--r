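# spikempc

Spike inference from calcium imaging, done as a control problem.

Two-photon calcium imaging reports neuronal activity through a slow,
noisy proxy: fluorescence of a calcium-bound indicator. Most downstream
analyses want the firing rate, not the fluorescence. spikempc recovers
the firing rate by modeling the calcium/indicator chemistry as a
mass-action ODE and treating the unknown rate as the *control input* that
a receding-horizon model predictive controller (MPC) must apply for the
model to track the measured trace. Unlike deconvolution or
supervised-learning approaches, every emitted rate estimate is causal
(fixed 60 ms lookahead, no backtracking), so the same machinery drives
real-time use and closed-loop stimulation, and every internal quantity —
free calcium, bound indicator — has a mechanistic meaning.

## The model and the controller

With `x` free calcium, `z` bound (fluorescing) indicator, total indicator
`L` conserved, binding/unbinding rates `k_f`, `k_r`, firing gain `α` and
extrusion rate `γ`:

    dx/dt = α s − γ x + k_r z − k_f x (L − z)
    dz/dt = k_f x (L − z) − k_r z

At each 10 ms sample the controller minimizes, over nonnegative rate
sequences `s` of length `n = 6`,

    Σ_{k<n} (z_k^sim − z_k^meas)² + r (s_k − s_{k−1})²  +  w_T (z_n^sim − z_n^meas)²

subject to the dynamics (`r = 0.01`), applies the first rate, advances
the model one step, and slides the window. Raw fluorescence passes
through a shifted sigmoid filter `σ(v) = 1/(1+e^{−(v+1)}) − h` with
`h = 0.15` and an automatic one-shot fallback to `h = 0.25` on
saturation. The gain `α` is auto-calibrated from 1–3 cells with paired
electrophysiology. Evaluation follows the standard benchmark protocol:
40 ms binning, Pearson correlation, and the Victor–Purpura spike distance
(unit cost per 10 ms move). A frequency-response module quantifies how
well state variables track sinusoidal rate drive across frequencies — a
tool for reasoning about indicator design.

The finite-horizon subproblems are solved in compiled code (RK4
single-shooting with exact tangent sensitivities + projected
Levenberg–Marquardt); a 60 s recording is processed in well under a
second on one core.

## Worked example

Generate a synthetic ground-truth recording (58 Poisson spikes over
60 s, realistic noise), infer rates, and score them:

```r
library(spikempc)

params <- cell_params(gcamp6s(), alpha = 50, gamma = 1)

spec  <- synthetic_spec(duration = 60, mean_rate = 1, noise_sigma = 1, seed = 42)
train <- generate_spike_train(spec)
rec   <- synth_recording(params, train, spec)

res <- infer_rates(rec$noisy, params, mpc_config())
res
#> <inference_result> 6000 steps, dt = 0.01 s; mean rate 1.12 Hz; no saturation

mcfg <- metric_config()
pearson(bin_downsample(res$s_hat, mcfg$bin_factor),
        bin_downsample(train, mcfg$bin_factor))
#> [1] 0.503
victor_purpura(rates_to_spikes(res$s_hat, mcfg), train, mcfg)
#> [1] 80
```

The inferred mean rate (1.12 Hz) sits near the generating 1 Hz; the
binned correlation of 0.50 against ground truth is in the range typical
for single noisy cells at this SNR, and the Victor–Purpura distance of 80
for 58 true spikes reflects the ±20 ms placement granularity of
bin-center spike emission (lower is better; an empty prediction would
score 58 at zero correlation, perfect timing would score near 0). For
real recordings, run `prepare_measurement()` (or `spike_inference()`,
which adds the saturation restart) on the raw trace first, and
`calibrate()` on a cell with ground truth to fix `α`.

A command-line front end covering the same pipelines (`infer`,
`calibrate`, `evaluate`, `simulate`, `freqresponse`) lives at
`inst/cli/spikempc.R`; spikefinder-style CSVs (columns = neurons, rows =
10 ms samples, NaN padding) are read and written by `read_recordings()` /
`write_results()`, with a key=value manifest for reproducibility.

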