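---
title: "Inferring firing rates from calcium imaging by model predictive control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring firing rates from calcium imaging by model predictive control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikempc)
```

## The model

Fluorescent calcium indicators report neuronal activity only indirectly:
an action potential raises intracellular calcium, calcium binds the
indicator, and the bound indicator fluoresces. spikempc models this chain
with mass-action kinetics. Writing `x(t)` for free calcium, `z(t)` for
bound indicator, and `y(t) = L - z(t)` for unbound indicator (the total
indicator concentration `L` is conserved), the binding reaction
Ca²⁺ + CI ⇌ CI* with forward rate `k_f` and reverse rate `k_r`, a
firing-rate drive `s(t)` scaled by a gain `α`, and first-order calcium
extrusion at rate `γ` give

$$
\dot x = \alpha s - \gamma x + k_r z - k_f x (L - z), \qquad
\dot z = k_f x (L - z) - k_r z .
$$

Units: time in seconds, rates in Hz, concentrations in normalized model
units (fluorescence is equated with `z`; no photon-physics model is
attempted). The GCaMP6s preset uses `k_f = 0.0514`, `k_r = 7.6`,
`L = 30`.

Two structural facts the package verifies rather than assumes:

* **Closed-form steady state.** Under constant drive `s`,
  `x* = αs/γ` and `z* = L k_f x* / (k_r + k_f x*)`; `z*` saturates at `L`
  only for infinite drive.
* **Unconditional stability.** The Jacobian at any steady state has
  trace `-(γ + k_f(L - z*) + k_r + k_f x*) < 0` and determinant
  `γ(k_r + k_f x*) > 0`, so both eigenvalues have negative real part for
  every admissible parameter set and drive. (Note the Jacobian at the
  origin is *not* triangular — `k_f L` sits off-diagonal — so its
  eigenvalues are not simply `{-γ - k_f L, -k_r}`; the package computes
  them numerically and the test suite checks the trace/determinant
  identities instead.)

## Inference as control

Given a measured bound-indicator trace, the firing rate is treated as the
unknown *control input* that makes the model reproduce the measurement.
At each 10 ms step the controller solves a finite-horizon problem over
the next `n = 6` steps (a 60 ms lookahead):

$$
\min_{s \in \mathbb{R}_+^n} \;
\sum_{k=0}^{n-1} \left( z_k^{sim} - z_k^{meas} \right)^2
+ r \left( s_k - s_{k-1} \right)^2
\;+\; w_T \left( z_n^{sim} - z_n^{meas} \right)^2
$$

applies only the first computed rate, advances the model one step, and
shifts the window. Emitted rates are never revised — the method is causal
with a fixed 60 ms effective lag, which is what makes it usable for
closed-loop stimulation (`track_reference()` swaps the measurement for a
desired trajectory).

Defaults and their meaning:

| parameter | default | meaning |
|---|---|---|
| `n` | 6 | horizon length (60 ms at 10 ms sampling) |
| `r` | 0.01 | smoothness weight on rate increments |
| `s_min`, `s_max` | 0, 1000 Hz | hard rate bounds (nonnegativity; solver safety) |
| `terminal_weight` | 1 | weight of the horizon-end tracking penalty |
| `substeps` | 2 | RK4 substeps per 10 ms control interval |
| `solver_tol` | 1e-6 | step-size convergence tolerance (Hz) |

**Terminal penalty.** The cost's final term is implemented as a weighted
squared tracking error at the horizon-end state. It approximates the
infinite-horizon value of leaving the horizon off-track and stabilizes
the short horizon; `terminal_weight` is exposed because other
realizations (e.g. a learned value function) are conceivable.

**Transcription and solver.** The dynamics inside the horizon are
discretized by single-shooting RK4 with *exact* forward sensitivities
propagated through the RK4 stages in tangent mode; the resulting
6-variable bound-constrained nonlinear least-squares problem is solved by
a projected Levenberg–Marquardt Gauss–Newton iteration, warm-started from
the previous horizon shifted by one step, with one restart from zero on
stalls and a zero-input candidate guard (so the reported per-step cost
never exceeds the do-nothing cost). We chose single shooting over
collocation deliberately: with a 2-state non-stiff model, six 10 ms
intervals and exact tangents, shooting is the simplest transcription that
is exact to RK4 order, and it keeps the per-step solve in the tens of
microseconds — a 60 s recording is processed in well under a second,
comfortably faster than real time.

**Stiffness guard.** The binding term `k_f x (L - z)` makes the system
locally stiff when large inputs push free calcium high. Every RK4
application bounds `h × (fastest local rate)` by 0.8, refining the
substep count as needed, so extreme-drive excursions (e.g. while tracking
an infeasible reference) remain numerically stable.

**State propagation.** Between solves the model state advances open-loop
under the applied rate (default). `reset_state = TRUE` instead re-anchors
the simulated indicator at each measurement; this trades noise rejection
for faster recovery from model mismatch and is exposed as a toggle
because either convention is defensible.

**Initial state.** With `init = "auto"` the first measurement sample is
taken as `z₀` (clipped below `0.95 L`, since the binding-equilibrium
`x₀ = k_r z₀ / (k_f (L - z₀))` diverges as `z₀ → L`) and `x₀` placed on
the z-nullcline, i.e. binding equilibrium at recording start. The
smoothness anchor at the first step is `s₋₁ = 0`, so a recording that
begins mid-burst shows a short ramp-in (about the horizon length at
calibrated gains).

## The measurement filter

Raw fluorescence is standardized per neuron (z-scoring by default; the
sigmoid's centering at −1 presumes roughly standardized input — min-max
and none are selectable because public benchmark traces arrive in
heterogeneous normalizations) and passed through the shifted sigmoid

$$ \sigma(v) = \frac{1}{1 + e^{-(v + 1)}} - h $$

which compresses extreme samples while keeping a linear mid-range. The
shift `h = 0.15` lowers the ceiling to `1 - h`; if the simulated
indicator still gets stuck near the ceiling (25 consecutive samples above
95% of it, i.e. 250 ms — long enough to exclude single-sample
transients), the pipeline restarts once with the aggressive shift
`h = 0.25` and reports which shift was used. Exactly one fallback pass is
ever taken.

## Calibration of the firing gain

With paired fluorescence and ground-truth spikes from 1–3 cells,
`calibrate()` fits the gain `α` (and optionally other parameters) by
maximizing the mean 40 ms-binned Pearson correlation between inferred
rate mass and ground-truth counts over a 16-point log-spaced grid,
followed by a parabolic-vertex refinement through the grid points around
the peak. The vertex fit replaces a line-search refinement on purpose:
the binned objective inherits small-scale roughness from spike
discreteness, and a line search chases those wiggles while the quadratic
fit averages over them at zero extra cost.

Two properties of this objective are worth understanding before trusting
a calibrated value:

* **Noise is what identifies α.** On the model's linear operating range
  the Pearson objective is scale-invariant, so on *noiseless* data a
  too-large gain is nearly free: the controller simply infers a scaled
  rate. What localizes the optimum is the trade-off the controller's
  smoothness penalty creates on noisy data — too small a gain
  over-smooths genuine transients, too large a gain tracks imaging noise
  as spurious activity. Synthetic calibration experiments therefore use
  noisy traces on the model scale (per-trace z-scoring would erase the
  amplitude information entirely).
* **A modest upward bias is structural.** Sharper tracking at larger
  gains correlates a little better until noise-tracking dominates, so the
  objective's argmax tends to sit 1.2–1.5× above the generating gain at
  realistic noise. The acceptance suite's recovery experiment (gain 50,
  three 180 s cells at 1 Hz Poisson firing, noise SD 3 ≈ 19% of the peak
  response) recovers the gain within a factor of 1.5; expect the same
  order of fidelity, not percent-level estimates, on real data.

Calibration without simultaneous ground-truth spikes is out of scope, as
is any per-dataset refitting of the indicator kinetics — the intended use
is fixed `k_f, k_r, γ` across datasets with `α` absorbing per-dataset
scale.

## Evaluation metrics

Following the public-benchmark protocol, rates and spike trains are
downsampled by a factor of 4 from the native 10 ms grid into 40 ms bins
(rate mass `Σ s·dt` per bin; trailing partial bins dropped with a
warning), compared by Pearson correlation, and alternatively by the
Victor–Purpura edit distance (insert/delete cost 1; moving a spike one
*native* timestep costs exactly 1, i.e. `q = 100 /s` — the native grid,
not the 40 ms bins, is taken as the "timestep", since that is the
acquisition step). `rates_to_spikes()` converts a rate trace to discrete
events by rounding per-bin mass (half-to-even) and emitting spikes at bin
centers; note the ±20 ms placement jitter this implies makes VP scores
conservative. `summarize_scores()` reports per-dataset and pooled
dispersion in the convention of benchmark tables.

## Frequency response and indicator design

Because the model is mechanistic, one can ask the inverse question: given
a firing-rate drive `s(t) = A sin(ωt) + c`, how well do the state
variables follow? `amplitude_ratio()` simulates from the steady state of
the mean drive, discards `max(10 periods, 60 s)` of transient, measures
half peak-to-peak amplitudes of `x`, `z` and `x + z` over the last 3 full
periods, and divides by `A`. Settledness is verified by comparing against
a window one period earlier (2% tolerance, one automatic horizon
extension, then an error carrying the partial result). Half peak-to-peak
was preferred over the FFT fundamental because the nonlinear response is
slightly asymmetric; the estimator is insensitive to the exact cutoff
once ≥ 5 periods are discarded. Drives with `c < A` would go negative;
they are clipped at zero with a warning by default (`clip_negative`
selectable), since firing rates cannot be negative.

For GCaMP6s the bound-indicator ratio falls off with ω — calcium dynamics
cannot keep up with fast rate modulation, which is precisely why inferring
`s` rather than reading fluorescence matters. `compare_indicators()` puts
a candidate indicator side by side with a reference across an ω grid
(natural-log spaced, 40 points over e⁻³..e³ rad/s by default) and reports
the binding affinity `k_d = k_f/k_r` of each.

**Choice of operating point.** The comparison defaults to a cell with
calibrated gain `α = 50`, extrusion `γ = 1`, and a sustained drive of
11 ± 3 Hz. This choice is deliberate and matters for the conclusions: a
low-affinity indicator (e.g. `k_f = 0.01`, `k_r = 10`, `k_d = 0.001`)
improves the low-frequency amplitude ratio *only* when the whole drive
range keeps baseline free calcium in the reference indicator's binding
saturation zone (for GCaMP6s, `x̄ ≳ k_r/k_f ≈ 148` model units; the
quasi-static gain is `(α/γ) L k_f k_r/(k_r + k_f x̄)²`). At that operating
point GCaMP6s has little headroom and the weaker binder responds more
linearly. With drives that dip to near-quiescence the ranking reverses
and the high-affinity indicator wins at DC. Equal `k_d` with different
absolute rates also gives measurably different sweeps — affinity alone
does not determine dynamics.

## The synthetic generator

`synthetic_spec()` + `generate_spike_train()` + `synth_recording()`
produce the fixtures every experiment runs on: an (in)homogeneous Poisson
train on the 10 ms grid (constant, piecewise or sinusoidal profile),
forward simulation of the ODE from the zero equilibrium by fixed-step RK4
at 1 ms substeps (finer than, and therefore a fair oracle for, the
controller's internal 5 ms discretization), and additive iid Gaussian
noise on the bound-indicator trace. Spikes enter as rate impulses through
`s` (one spike in a 10 ms step reads 100 Hz for that step), not as state
jumps. Every draw is governed by the mandatory seed (noise uses
`seed + 1` so spike and noise draws are independent but jointly
reproducible).

What the generator emulates: indicator kinetics, spike-driven calcium
influx, additive measurement noise at realistic SNR. What it does not:
photon shot noise, bleaching, motion artifacts, the nonlinear
fluorescence–indicator relationship of real sensors, or slow baseline
drift. Green synthetic tests therefore certify the *inference machinery*
— identifiability, causality, metric correctness — not end-to-end
accuracy on real recordings, which additionally depends on the filter and
on calibration quality.

## Problem sizes used by the test and acceptance suites

Chosen as the smallest experiments that exercise each claim cleanly:
steady-state and stability checks on closed forms (instant); a 60 s
piecewise-constant recovery run for controller identifiability (mean
absolute relative error below 10% away from rate switch points, at the
calibrated gain 50); the three-cell 180 s calibration experiment above;
exhaustive Victor–Purpura verification against an order-preserving
matching oracle for all train pairs of up to 5 spikes on a 5-point grid;
and 9-point ω sweeps for the frequency-response claims.

## Known limitations

* Fluorescence is equated with bound indicator; a nonlinear
  fluorescence model would change the filter, not the controller.
* The 60 ms horizon trades accuracy for causality: step changes in rate
  are localized to within ~n steps but the first samples of a recording
  ramp in from the `s₋₁ = 0` anchor.
* Short-horizon tracking of step references overshoots through the
  calcium→indicator cascade (raising `z` requires raising `x`, which can
  then only be cleared at rate `γ`); this is physical, not numerical.
* The calibration objective's structural upward bias (above) caps the
  fidelity of recovered gains at roughly a factor ~1.5.
* Victor–Purpura scores computed from bin-center spike emission are
  pessimistic by up to the bin half-width per spike.
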