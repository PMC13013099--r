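---
title: "Context-modulated adaptation in spiking networks under weight perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-modulated adaptation in spiking networks under weight perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(contextsnn)
```

## The problem and the model

Analog implementations of neural networks store synaptic weights in physical
device states that drift — with time, temperature, or cumulative radiation
dose. The resulting weight perturbations degrade inference. `contextsnn`
studies a run-time mitigation that leaves the weights untouched: a global
scalar *context* signal `c`, proportional to the current perturbation level
(think of a dosimeter reading mapped to [0, 1]), is broadcast to all neurons.
Each neuron owns a trainable projection `p_j` and shifts one of its intrinsic
parameters in proportion to the context:

* threshold mode: `v_th_j = v_th_base + p_j c`
* time-constant mode: `tau_j = max(tau_base + p_j c, tau_min)`

The network learns `p` jointly with its weights while experiencing simulated
perturbations during training, so that at deployment the single scalar `c`
steers the whole population into a regime that compensates the drift.

The neuron is the standard discrete-time leaky integrate-and-fire model.
The integration scheme is forward Euler with `dt = 1` frame — stimulus frames
define the clock, and the membrane time constants are expressed in frames.
`dt` is exposed so that single-neuron simulations can be refined toward the
continuous limit; the FI-curve tests integrate at `dt = 0.01` and agree with
the closed-form rate `1 / (tau ln(I / (I - v_th)))` to better than 5%.
Spikes use a hard Heaviside forward pass with reset-to-value (`v := v_reset`
on spike); the backward pass uses the SuperSpike surrogate
`1 / (beta |v - v_th| + 1)^2`. Gradient does not flow through the reset gate
(`z` is treated as given in the reset equation), the common stabilizing
convention for surrogate-gradient BPTT.

## Tunable parameters

| parameter | units | default | why |
|---|---|---|---|
| `v_th_base` | V | 1.0 | base firing threshold |
| `tau_m_base` | frames | 4 (feedforward), 16 (recurrent) | membrane time constant per topology |
| `dt` | frames | 1 | stimulus frames define the clock |
| `tau_min` | frames | 0.1 | clamp preventing `tau + p c` from changing sign |
| `beta` | — | 100 (package default); 10 in the tiny preset | surrogate slope; see "Desk-scale calibration" |
| `input_gain` | — | 12 | current-injection gain of the frame encoding |
| perturbation grid | — | 10 levels on [0, 1]; doses 0–1000 krad in 100 krad steps | evaluation grids of the two perturbation models |
| learning rate | — | 0.001 (package default); 0.1 / 0.02 in the tiny preset | SGD + momentum 0.9, halved after 10 stalled epochs |

Thresholds are deliberately *not* clamped: `p c` may push a threshold below
the reset voltage, in which case the unit fires every step — legal dynamics,
and the learned solutions do use signed shifts. The time constant is clamped
at `tau_min` because a negative `tau` flips the sign of the leak and
destabilizes the forward pass; the clamp also zeroes the corresponding
gradient so the optimizer cannot push further into the clamped region. Time
constants are modulated directly (`tau + p c`); an inverse parameterization
(shifting the leak rate `1/tau`) is available via `tau_param = "inverse"`,
which expresses the same family in units where the useful `p` magnitudes are
closer to the threshold mode's.

## Perturbation models

Both models realize one noise draw per trial and hold it constant over all
timesteps — slow drift, not fast synaptic stochasticity. Draws are pure
functions of `(seed, tensor name, shape)`, so trials replay bit-exactly.
Perturbations apply to every convolution kernel (input and recurrent) and to
the final linear readout weights; biases and normalization parameters are
never perturbed. During training, a fresh draw is frozen per minibatch and
gradients flow through the perturbed weights to the ideal weights (including
the `c sign(w) phi` term of the multiplicative model).

The Gaussian model `w' = w + c |w| phi` increases the spread but not the mean
of each weight. The dose model adds `N(mu(w, d), sigma(w, d))` with surfaces
interpolated bilinearly from a rectangular lookup table. The shipped table is
**synthetic**: its mean component drifts each weight toward a saturation
value with an exponentially saturating dose dependence, and its spread grows
modestly on top of an intrinsic write-error floor. It reproduces the
qualitative shape of published charge-trap (SONOS) radiation responses —
dose-increasing mean shift, modest spread growth, write error at dose 0 —
but is not fit to measured device data; users supply their own tables in the
same CSV format (`weight,dose_krad,mu,sigma`).

One arithmetic note: the dose grid "0 to 1,000 krad in 100 krad steps"
contains 11 points, which is what the package uses; descriptions of this
design sometimes count it as 10 levels.

## Architectures and training protocol

Both topologies are three-block convolutional SNNs ending in a single
flatten + linear + leaky-integrator (LI) readout. Feedforward blocks use
per-channel batch normalization; recurrent blocks do not (keeping every
inter-block tensor binary) and instead add a second convolution over the
block's previous-timestep spikes as an additive current stream. Modulation
granularity is one `p` per output channel of each LIF block (shared over
spatial positions); the non-spiking readout is not modulated. Classification
heads read the LI state at the final timestep; tracking heads read it at
every timestep. Tracking targets are normalized to [0, 1] internally and all
reported errors are converted back to squared pixels.

Training is two-phase. Phase one pretrains the base network without
perturbation or modulation; its batch-normalization statistics are then
frozen so later perturbations cannot leak into the normalization constants.
Phase two re-casts the pretrained weights as one of the Table-2-style
variants and trains further: per minibatch a context level is sampled
uniformly from the level grid restricted to `[0, c_max]` (a fixed-at-max
policy is available), perturbation-bearing variants get a fresh frozen draw,
and modulated variants train `p` jointly with the weights. The sham variant
receives the sampled context but no perturbation — the control for "more
trainable parameters".

## Desk-scale calibration (the tiny preset)

All tests and examples run the `tiny` preset: 16x16 small-object-tracking
videos of 50 frames (constant-velocity single-pixel object, speed 0.2
px/frame, Gaussian positional jitter, reflective walls, smooth static
clutter plus per-frame noise), 48 training / 16 hold-out videos, a 4/8/16-
channel 3-block network, 3 seeds, 30-epoch phases. Several choices deviate
from the full-scale defaults and were made once, on training-dynamics
grounds, when the preset was designed:

* **Surrogate slope `beta = 10`** (default 100). The SuperSpike derivative at
  `beta = 100` is below 1e-4 for any membrane more than 0.1 V from
  threshold; with only 4–16 units per layer and ~200 gradient updates, no
  usable learning signal crosses two spiking layers. A shallower slope is the
  standard remedy for small surrogate-gradient networks.
* **Spike-rate-corrected initialization.** He-style initialization assumes
  unit-variance inputs; binary spike inputs firing at rate rho have variance
  ~rho, so kernels consuming spikes are scaled by `1 / sqrt(rho)` with
  rho = 0.005 in the preset. Without it the deeper blocks are silent at
  initialization and remain untrainable.
* **Input gain 12** maps the task's pixel contrasts onto currents that drive
  first-layer units near threshold.
* **Learning rates 0.1 (pretrain) / 0.02 (adapt)** with gradient-norm
  clipping at 5 / 2: ~200 updates must converge where the full-scale setup
  takes 100 epochs at lr 0.001. The adapt phase clips harder because batches
  at high perturbation levels otherwise dominate every update.
* **Projection learning-rate scale.** `p` lives in different natural units
  than the weights: a threshold projection moves the threshold by `c` volts
  per unit of `p`, while a tau projection moves the per-step leak factor by
  only `c dt / tau^2` (~0.004). The preset trains `p` with a learning-rate
  multiplier of 25 (threshold) and 6000 ≈ 25 tau^2 (tau), the natural-units
  correction.
* **Tracking readout tau = 4 frames.** An LI readout with tau 16 lags a
  moving object by ~`speed * tau` pixels, which at desk scale is the size of
  the whole error budget; classification keeps the slow accumulating readout
  (tau = `tau_m_base`).

## What the synthetic tasks do and do not emulate

The SOT generator reproduces the *structure* of a remote-sensing tracking
problem — a weak point target over clutter with temporal continuity — but
its clutter is a smooth random field, not natural imagery, and its motion
model is simple. The toy classification task shares only the pipeline shape
of a natural-image benchmark: distinct smooth templates plus pixel noise,
linearly separable by design (a nearest-template observer is perfect at zero
noise). Passing the desk-scale recovery experiment therefore demonstrates
that the mechanism — context-modulated thresholds or time constants
recovering performance under trial-frozen weight perturbations in recurrent
networks — operates end to end; it does not predict accuracy numbers on
natural-image benchmarks or real device data.

## Numerical choices and degenerate inputs

* Max-pool ties break toward the first candidate in (row, column) order;
  spike tensors are binary, so ties are common and the rule keeps replays
  bit-exact.
* The softmax cross-entropy clamps probabilities at 1e-12; training aborts
  with a seed/epoch diagnostic if a loss turns non-finite, and the forward
  pass aborts naming the first offending layer and timestep if an activation
  does.
* PCA embeddings fix component signs by making each component's
  largest-magnitude loading positive; rank-deficient records return fewer
  components with a warning. "Per-trial" trajectory PCA is fit once per
  condition on the pooled (trial x timestep) matrix and trials are then
  projected individually — the only reading under which trial locations are
  comparable across trials, which the class-separation score requires. The
  score itself is a mean silhouette over final-timestep positions (0 when
  all classes coincide; rotation invariant).
* The level-0 evaluation applies no draw at all, so level 0 is exactly the
  clean model, not a zero-variance random draw.
* Evaluation averages 5 independent draws per grid cell (draw variance at
  high levels is substantial); reported cell values are means over seeds
  with per-seed, per-draw values retained in the long-format grid.

## Known limitations

* The desk-scale experiment shows orderings (degradation, recovery), not
  effect sizes transferable to full-scale benchmarks.
* The latent class-separation silhouette is a blunt summary: at desk scale
  (a 4/8-channel recurrent network, 2 principal components, per-trial frozen
  draws at the highest perturbation level) it is dominated by draw
  variability and does not reliably resolve the context-vs-perturbed
  contrast that the accuracy metric on the same models shows clearly; the
  corresponding test documents this as an open gap rather than relaxing the
  check.
* The dose table is synthetic; conclusions about real irradiated devices
  require a measured table.
* Batched training maps "trial" to minibatch for draw freezing (per-sample
  draws are available but slower).
* Feedforward networks are not expected to benefit from context modulation —
  the package reproduces this null result but does not investigate deeper
  feedforward mitigation strategies.
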