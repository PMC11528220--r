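---
title: "Methods: latent dynamics models on LFP band power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent dynamics models on LFP band power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lfpdyn)
```

This vignette is the package's account of its science: the model and its
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations.

## The problem and the modeling idea

Intracortical BCIs usually decode from threshold-crossing spikes, whose
acquisition (30 kHz broadband) dominates the implant's analog front-end
power. LFP band power — here the 150–450 Hz band computed from a 2 kHz
signal — costs an order of magnitude less to acquire but, used directly as
a decoding feature, carries less usable information per bin.

The package's core method closes that gap with a sequential variational
autoencoder over neural population dynamics. Its input is the LFP band
power stream `p(t)` (channels × 20 ms bins); its objective is Poisson
reconstruction of the simultaneously recorded spike counts `s(t)`:

* a **bidirectional GRU encoder** reads the full input window and emits a
  Gaussian posterior over the generator's initial condition `x(0)`;
* an optional **controller GRU**, conditioned on the per-step encoder
  features and the previous factors, emits a Gaussian posterior over a
  low-dimensional inferred input `u(t)` at every step;
* a **generator GRU** evolves `x(t)` from `x(0)` driven only by `u(t)` —
  it never sees the data directly, so its state must explain the window
  through its own dynamics;
* **factors** `f(t)` are a linear readout of the generator state, and
  per-channel rates are `exp`-linear in the factors, giving strictly
  positive Poisson intensities in spikes/bin.

The training loss is the Poisson negative log likelihood of `s(t)` under
the rates (including the `log s!` term, so reported values are true NLLs)
plus KL divergences of the initial-condition and inferred-input posteriors
from their priors, plus L2 penalties on the recurrent weights. Training
uses the reparameterization trick (posterior samples); inference uses
posterior means. After training, only the low-power LFP stream is needed
to produce denoised firing-rate estimates for decoding.

Key assumptions: population activity is driven by low-dimensional latent
dynamics evolving smoothly at the 20 ms timescale; spiking is
conditionally Poisson given the latent state; and the LFP band power
carries enough information about that state to support reconstruction —
the method tests this last assumption empirically rather than assuming it
away.

## Priors and architectural choices

The initial-condition prior is a unit Gaussian; inferred inputs have a
zero-mean unit Gaussian prior per step with no autoregressive structure.
This is the simplest faithful variant of the model family; an
autoregressive input prior adds coupling that desk-scale data cannot
constrain. The recurrent cell is a GRU throughout (`cell` is a config
field so the lineage is explicit). With `co_dim = 0` the controller and
its parameters do not exist and the generator is fully autonomous.

Both the hand-written R implementation and a compiled (RcppArmadillo)
implementation of the forward/backward pass ship in the package. The
compiled path is what `train_dynamics()` and the inference functions use;
the R path is the reference the test suite checks it against, alongside a
central-difference gradient oracle.

## Tunable parameters

From `model_config()`, with units and rationale:

| Parameter | Default | Why |
| --- | --- | --- |
| `encoder_dim`, `generator_dim` | 48, 48 | Desk-scale: trains on one CPU in ~3 minutes while leaving capacity headroom over the generator's 4-D synthetic latents; larger models mostly buy memorization here. |
| `controller_dim`, `co_dim` | 24, 2 | Two inferred-input dimensions suffice to signal condition onsets that fall mid-window; the controller is the mechanism that lets an otherwise-autonomous generator handle trial boundaries. |
| `ic_dim` | 24 | Initial-condition capacity; generous relative to the latent dimensionality so the encoder is not the bottleneck. |
| `factor_dim` | 8 | Twice the synthetic latent dimension; factors are the low-dimensional interface decoders consume. |
| `kl_weight_ic`, `kl_weight_co` | 0.05 | The KL terms weigh against a *summed* per-segment Poisson NLL whose learnable margin is a few tens of nats, so useful weights are small. Chosen by validation NLL on synthetic sessions: weights near 1 collapse the posteriors to the prior (the model converges to a homogeneous-Poisson solution); results are flat over roughly 0.02–0.1. |
| `kl_warmup_steps` | 100 | Linear warm-up; lets reconstruction structure form before the KL pressure arrives. Best-model selection only considers epochs after warm-up, when the validation ELBO is comparable across epochs. |
| `l2_gen`, `l2_con` | 1e-4 | Mild smoothness pressure on recurrent weights. |
| `dropout` | 0.05 | Input dropout; the KL terms and the data volume are the dominant regularizers. |
| `learning_rate`, `lr_decay` | 1e-2, 0.999 | Adam; the gradient-norm clip (200) absorbs the occasional large step. |
| `batch_size`, `max_epochs` | 64, 150 | About 900 gradient steps on the default synthetic session; validation loss bottoms out within the first third and the best-validation weights are returned. |
| `jitter_bins` | 2 | Spikes input only: every training step independently displaces each input spike by an integer offset uniform in ±2 bins (clipped at window edges, target untouched). Decorrelates precise spike timing across channels. |
| `valid_frac` | 0.2 | Seeded shuffle; best-validation weights are returned. |

Windowing follows `segment_continuous()`: 1000 ms windows, 200 ms overlap
for structured reach-like sessions (350 ms for less structured data), a
final partial window dropped. Causal inference (`infer_causal()`) emits
one bin per step from the trailing window using posterior means — outputs
at bin *t* depend only on data at or before *t* — and acausal inference
(`infer_acausal()`) merges overlapping windows by keeping, for each
session bin, the value from the window where that bin has the most left
context (ties to the earlier window).

## What the synthetic generator emulates

`generate_session()` produces the statistical structure the method
assumes, with full ground truth:

* **Latents**: block-diagonal 2-D rotations with per-bin decay 0.9 and a
  300 ms period (extra blocks, if `latent_dim > 4`, spread over 150–400
  ms). Each trial adds a condition-dependent impulse — directions on a
  circle of `n_conditions` angles — to a continuously evolving state, so
  movement structure and trial boundaries coexist in one continuous
  session, which is exactly what the windowed model must cope with.
* **Behavior**: velocity is a linear readout of the latent coordinates
  whose impulse response is `decay^t * sin(omega t)` — a bell-shaped speed
  profile peaking at `peak_speed` (10 cm/s) — plus white noise
  (0.2 cm/s). Ground-truth movement onsets are computed from the
  noiseless speed with the same 70%-of-peak crossing rule the event
  detector uses, so onset-recovery tests compare like with like.
* **Spikes**: rates are `exp(W_r z + b_r)` with readout rows of fixed norm
  `rate_gain = 3` in random directions — every channel modulates by the
  same motor-cortex-like log-depth (peaks of tens of Hz over a 10 Hz mean,
  no heavy-tailed outlier channels) — calibrated per channel so the
  session-mean rate equals `base_rate_hz` (10 Hz); Poisson draws at 1 ms.
  A configurable fraction of timesteps receives coincident artifacts
  (spikes added on 60% of channels) and one channel is duplicated, so the
  quality-control rules have real defects to find.
* **LFP band power**: each channel passes a sparse non-negative mixture
  of the realized 20 ms multiunit counts of a few nearby spike channels
  through a softplus, then multiplies slow drift
  (`1 + drift_amp * sin(2*pi*t/period)`, default 20% at a 6-minute
  period, exercising the 3-minute causal z-score) and lognormal noise
  whose variance is the softplus drive's log-variance divided by
  `coupling_snr`. Driving power from realized spiking — rather than
  noiselessly from the latent state — reflects what the 150–450 Hz band
  physically is (spike-band energy) and preserves the regime the method
  addresses: band power is a noisy, partially redundant correlate of
  spiking, so direct linear decoding from smoothed power underperforms
  rates reconstructed by a dynamics model. A noiselessly-coupled variant
  (`coupling_snr = Inf`, `drift_amp = 0`) uses the expected counts and
  makes power a deterministic softplus readout of the latent trajectory,
  which the tests exploit.

What it does **not** emulate: biophysical LFP (no volume conduction,
no 1/f spectrum — band power is generated at the feature level, with a
separate sinusoid fixture exercising the STFT path); electrode
nonstationarity beyond smooth multiplicative drift; correlated noise
across behavioral dimensions; speech audio beyond a piecewise envelope
fixture. Passing tests therefore demonstrate that the machinery recovers
structure *in the regime the method assumes*, not that real recordings
satisfy those assumptions.

The default session is 240 trials x 1.6 s (~6.4 minutes, 19,200 bins),
~25 spiking and 24 LFP channels (with a 128-neuron hidden population
behind the band power) — long enough that a model of the default size
generalizes rather than memorizing segments, while the full
train/infer/decode loop still runs on one CPU in a few minutes.

## Numerical choices

* STFT windows are rectangular (the stated 5 Hz frequency resolution is
  exactly 1/T only for a rectangular window); a frequency component
  belongs to a band if `lo <= f < hi`, one-sided, no doubling — absolute
  scale cancels under log + z-score.
* The causal z-score uses the trailing 3-minute window including the
  current bin; before the window fills it uses all history with a minimum
  of 10 bins, emitting 0 earlier; the zero-variance guard is `eps = 1e-8`
  in both the log clamp and the denominator. The rolling sums are
  computed on first-bin-centered values to avoid catastrophic
  cancellation without reading future bins.
* Resampling is rational polyphase FIR (cutoff 0.9x the new Nyquist,
  symmetric taps, delay-compensated); notch filters are 2nd-order RBJ
  biquads with Q = 35 at powerline harmonics below Nyquist.
* Correlated-channel removal is greedy: compute the Pearson matrix on the
  1 ms raster once, repeatedly drop the channel in the most
  above-threshold pairs (ties to the lower index) until clean. This
  reading of "remove any channels involved" keeps more channels than
  removing both members of each pair.
* A speed "crossing" is the first bin at or above threshold whose
  predecessor is below; a trial whose search window starts above
  threshold has no defined crossing and is rejected. Acceptance requires
  the forward-scan and backward-scan crossings to coincide.
* Envelope differentiation is a first difference scaled to per-second
  units; peaks are strict local maxima with 60 ms minimum separation, and
  the 3.5 threshold applies to the raw derivative magnitude
  (configurable).
* The Wiener penalty is read as `P = lam * I` with a zero at the bias on
  the normal-equation diagonal — the sweep range 100–1000 is a
  conventional ridge magnitude; the literal `R'R` reading (penalty
  `lam^2`) is available via `penalty = "rtr"`.
* Cross-validation folds are contiguous time blocks and training rows
  whose history overlaps a validation block are dropped, preventing
  leakage through the lagged design; the final report comes from a
  held-out tail never touched during the sweep. Held-out R² may be
  negative and is reported as-is.
* Posterior log-variances are clamped to ±8 and log-rates to 12 (with
  gradient masking) purely as overflow guards.
* Quantization floors `(x - min)/(max - min) * 2^b` and clamps to
  `2^b - 1`; constant channels map to 0.

## Limitations

* Hyperparameter search (population-based or grid) is out of scope; the
  defaults above were fixed once on synthetic data, and a user-declared
  grid can be run serially through ordinary R loops.
* Causal inference re-runs the trailing window per emitted bin; it is
  batched but still linear in session length times window length, so it
  is intended for short streams or online-style evaluation, with acausal
  merged inference as the bulk path.
* The PSTH R² of *any* rate estimate against empirical smoothed spikes is
  ceiling-limited by Poisson noise in the condition averages (about a
  dozen trials per condition at 10 Hz in the default session); comparisons
  against the generator's ground-truth rates do not have this ceiling,
  and the test suite uses both where each is meaningful.
* Multi-session stitching, streaming acquisition, and NWB compliance are
  non-goals; the session container is a validated single-file native R
  serialization with an explicit schema version.
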