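---
title: "From RFID backscatter to spiking inference: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RFID backscatter to spiking inference: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neorespire)
```

## The problem

Apnea of prematurity — a pause in breathing of 15–20 s or more — must be
detected promptly in premature newborn infants. A battery-less wearable
antenna (a knitted RFID tag on the belly) makes this possible without wires:
an interrogator polls the tag tens of times per second, and chest-wall
motion stretches the antenna, modulating the gain and return loss of the
backscattered signal. Classifying one-second windows of received signal
strength (RSSI) into breathing vs non-breathing is then a bivariate binary
time-series classification problem. Because the eventual inference platform
is an energy-constrained wearable, the package carries the classifier
through three inference regimes — full precision, k-bit quantized, and a
rate-coded spiking network for event-driven neuromorphic hardware — with a
spike-count energy model to compare them.

`neorespire` implements the whole chain: synthetic data generation,
feature engineering, a small 1-D CNN, quantization, spiking conversion with
a threshold design-space explorer, metrics, and energy accounting, wired
together by `run_pipeline()`.

## The synthetic recording and what it emulates

No recording of the original mannequin protocol is publicly available, so
the package ships a generator that emulates the protocol's statistical
structure:

* a programmable timeline alternating breathing at 31 breaths/min with
  apnea pauses of 30, 45 and 60 s, tiling one hour by default
  (`breathing_protocol()`; the breathing-segment lengths between pauses are
  not specified by the protocol description, so the default repeats 120 s
  segments — a choice, recorded here, not a measurement);
* interrogations at an effective 28 Hz per tag (jittered-uniform arrivals
  by default, Poisson optionally), round-robin channel hopping over 50
  equally spaced channels in 902–928 MHz, one dwell per hop;
* received power from the radar-cross-section link budget
  \[ P_{Rx} = P_{Tx} G_{reader}^2 G_{tag}^2 R \left(\frac{\lambda}{4\pi r}\right)^4, \]
  with the current hop channel's wavelength; during breathing the tag gain
  and return loss are modulated sinusoidally, \(G_{tag}(t) = G_0 (1 + m
  \sin 2\pi f_b t)\) and likewise for \(R\), with depth \(m = 0.05\);
  during apnea the modulation amplitude is zero;
* additive Gaussian noise on the dBm scale, default sd 0.1 dB. The depth
  \(m = 0.05\) implies a \(\approx 0.63\) dB peak RSSI modulation
  (\(30\log_{10} 1.05\)); the original de-oscillated traces show the
  breathing oscillation clearly dominating the signal, and a 0.1 dB noise
  floor reproduces that amplitude ratio. This is the single most important
  generator constant: it sets the difficulty of the whole downstream task.

The generator does **not** model multipath fading, tag collisions,
interrogator RSSI quantization, infant motion artifacts, or phase/Doppler
observables. Synthetic windows are therefore cleaner than real ones:
passing tests demonstrate that the pipeline's machinery is correct and that
its comparative claims (quantized vs spiking energy/accuracy orderings)
hold under the stated conditions — not that the reported accuracies would
be attained on real infants.

## Features

Feature 1 is the de-oscillated reflected signal strength. The link budget
is rearranged to isolate the wearer-state terms,
\[ \zeta = G_{tag}^{-2} r^4 R^{-1} = P_{Tx} G_{reader}^2 P_{Rx}^{-1}
   (\lambda/4\pi)^4 , \]
and the default Feature 1 is \(10\log_{10}\zeta\): its \(\lambda^4\) factor
cancels the channel-hop dependence of \(P_{Rx}\) exactly, which is the
purpose of the feature — the interrogator-controlled constants drop out
after standardization. A second variant (`method = "residual"` in
`compute_features()`) instead subtracts the per-hop residual
\(\delta(f) = -10\log_{10} f^4/(f - 0.5\,\mathrm{MHz})^4 \approx -0.0094\)
dB from the raw RSSI; the closed form is implemented and tested, but note
that removing a per-observation constant of that size cannot flatten the
\(\approx 0.5\) dB sawtooth the 26 MHz hop span induces, so the zeta
variant is the default.

Feature 2 (`rssi_from_min`) is the current Feature 1 value minus the
minimum over a trailing (causal) window of 28 samples (≈1 s at the
effective rate): near zero during apnea, and on the order of the modulation
amplitude during breathing. It is translation-invariant, so the additive
constants in Feature 1 are irrelevant to it.

Records are reduced to half-open 1-s windows \([t, t+1)\) with no overlap;
each window is the per-feature mean of its samples, labelled by the
majority ground-truth state over the window interval. Exact ties (possible
only for a boundary splitting a window exactly in half) resolve to the
safety-critical non-breathing class. Windows with no samples are dropped
with a warning. Features are standardized to zero mean and unit
**population** standard deviation (divide by \(n\)); the scaler is fitted
on the training partition only. The train/test split is random (3:1, test
size \(\lceil N/4\rceil\)) under a seed; a chronological split is available
via a flag since the original description does not say which was used.

## The classifier

`build_1dcnn()` constructs the canonical architecture: length-2 input (the
two window features) with one channel → Conv1D(64 filters, kernel 1, ReLU)
→ MaxPool1D(pool 1, stride 1 — the identity) → Flatten → Dropout(0.01) →
Dense(200, ReLU) → Dense(100, ReLU) → Dense(1, sigmoid). The parameter
count is exactly 46,129 (128 + 25,800 + 20,100 + 101), which pins the
model-size table (`model_size_bits()` = count × k bits). A single sigmoid
output unit thresholded at 0.5 is used rather than a two-unit softmax: two
softmax units would give 46,230 parameters, inconsistent with the published
model sizes, so the count wins. With kernel and pool size 1, the
convolution is a per-position linear map with weights shared across the two
feature positions — the tests verify it against an explicit loop-based
oracle.

Training minimizes binary cross-entropy (the standard pairing with a
sigmoid output) with Adam at learning rate 0.001, batch size 5, shuffling
each epoch, at most 100 epochs — and early stopping: training halts after 5
consecutive epochs without validation-loss improvement, restoring the
best-validation weights. When no validation set is passed, 10% of the
training partition is held out internally. All randomness (initialization,
shuffling, dropout, the internal split) flows from one seed.

`grid_search()` scores every (epochs, learning-rate) combination by
validation misclassification, with ties broken toward fewer epochs and
smaller rate so the result is invariant to grid ordering; early stopping is
disabled inside the search so each epoch budget is honoured.
`repeated_kfold()` reports the mean fold accuracy, the sample standard
deviation of per-repeat means, and the standard error \(\sigma/\sqrt{n}\);
with a single repeat \(\sigma\) over repeats is undefined, so the fold-level
standard deviation is reported with a `degenerate` flag and a warning.

## Quantization

The quantizers follow fixed closed forms, everywhere rounding half away
from zero (base R's `round()` rounds half to even, which would change
lattice values at exact midpoints — ties are rare but must be
deterministic):

* unit lattice: \(Q(z) = \mathrm{round}((2^k - 1) z)/(2^k - 1)\) on
  \([0,1]\) — idempotent, monotone, \(2^k\) points;
* weights: \(w_q = Q(\tanh(w)/(2\max|\tanh w|) + 1/2)\), per tensor; the
  largest-magnitude weight always lands on a lattice endpoint. Biases are
  quantized like weights at the same k. De-quantization inverts the affine
  map *and* the tanh using the stored per-tensor normalizer, so at large k
  the de-quantized weights equal the originals to machine precision —
  inverting only the affine map would leave weights tanh-squashed and the
  64-bit model would not reproduce the full-precision forward pass;
* activations: clip to \([0,1]\), then the unit lattice. The hidden ReLU
  activations are quantized during `quantized_forward()`; the final sigmoid
  stays in full precision (quantizing a probability head gains nothing and
  destroys score resolution);
* `mantissa_quantize()` implements fixed-point quantization with b integer
  bits, saturating at \([-2^{k-1}, 2^{k-1}-1]\) steps.

Post-training quantization is the supported path. Note the activation clip
means the high-precision limit `quantized_forward(k = 64)` equals the
full-precision forward only while hidden activations stay inside
\([0, 1]\); the tests construct that regime explicitly.

## Spiking conversion

`convert_to_snn()` maps the trained network onto integrate-and-fire (IF)
neurons with soft (subtract-threshold) reset — no leak, so with zero input
the membrane potential is unchanged, and a constant per-step drive \(c\)
produces \(\lfloor cT/V_{th}\rfloor \pm 1\) spikes in \(T\) steps. The
subtract reset (rather than reset-to-zero) is what preserves the
rate ∝ activation proportionality the conversion relies on; reset-to-zero
is available on the single-neuron API.

Three calibration devices, all computed on a calibration batch (the
training partition in the pipeline):

* **Data-based weight normalization.** Each layer's weights are rescaled by
  \(\lambda_{l-1}/\lambda_l\), where \(\lambda_l\) is the maximum
  activation of layer \(l\) on the calibration batch, so normalized
  activations — and hence firing rates at threshold 1 — lie in \([0,1]\).
* **Affine range encoding at both ends.** Standardized inputs can be
  negative, and spike rates cannot: inputs are mapped affinely from their
  calibrated range onto \([0,1]\) before Bernoulli (or deterministic
  evenly spaced) rate encoding, with the offset absorbed into the first
  layer's bias terms. The signed output pre-activation \(z\) is treated
  symmetrically: it is mapped through the calibrated symmetric range
  \([-\max|z|, +\max|z|]\), which places the classifier's decision boundary
  \(z = 0\) exactly at half the maximum output rate — so decoding "label 1
  iff output rate ≥ half the calibrated maximum" reproduces the analog
  decision rule.
* **Spike-borne biases.** Biases are delivered as weighted spikes from a
  chain of always-on auxiliary neurons (level \(l\) fires at rate
  \(1/V_{th}^l\)), not as constant currents. A constant current keeps an
  \(O(1/V_{th})\) bias floor while synaptic signal attenuates through
  \(L\) layers as \(O(1/V_{th}^L)\); sweeping the threshold would then
  drown the signal in the bias floor and collapse every prediction to one
  class already at \(V_{th} = 2\). With spike-borne biases, bias and signal
  attenuate identically, the half-maximum decision rule stays centred at
  every threshold, and accuracy degrades gracefully as spike-count
  resolution (\(\sim T/V_{th}^L\)) runs out — the behaviour a threshold
  design-space exploration is meant to show. Both bias representations are
  standard in rate-coded conversion; this package commits to the spiking
  one.

Decision-rate calibration reruns the stored calibration batch through the
simulator at the requested threshold and horizon, so the decoder always
matches the operating point; with no surviving calibration spikes the
threshold degenerates to zero and predictions collapse to the breathing
class, sending accuracy to that class's prevalence — the expected
large-threshold limit.

Simulation is synchronous with unit timestep, vectorized across samples.
The module-level default horizon is \(T = 1000\) steps per window; the
pipeline's selected design point is \(T = 200\) for test-set inference and
\(T = 100\) inside the threshold sweep — deliberately small horizons, since
low spike counts are precisely what makes spiking inference cheap, at the
cost of rate resolution. The threshold grid default is 1–10 in the
dimensionless membrane units of the converted weights (the "mV" labels of
neuromorphic hardware do not attach to unitless trained weights; we treat
the threshold as dimensionless).

`threshold_sweep()` evaluates fixed evaluation sets; the pipeline's
`sweep_design_space()` instead draws a fresh evaluation batch per
(threshold, size) cell so that small-sample cells carry genuine sampling
variability. The variance contrast between small and large evaluation
samples is a weak-signal property: the between-regime spread (live vs
silenced thresholds) is common to both columns, and only the sampling
noise differs, so the contrast is asserted under the pipeline's fixed
seeds rather than claimed universally.

## Energy accounting

Spiking inference energy is spike-count arithmetic:
`total = n_spikes × e_spike + n_routing × e_route`, with the neuromorphic
per-event constants 23.6 pJ/spike (calibrated at a 30 Hz spike frequency —
a calibration condition, not enforced at simulation time) and
3 pJ/routing-event. Routing events default to spike × fan-out, one event
per downstream synapse, with fan-outs derived from nonzero weights;
conservation (routing = Σ count × fan-out) is a tested invariant.

Conventional inference uses a parametric per-operation model:
`e_mac(k) = 2 k²` pJ per multiply-accumulate and `e_mem(k) = 1 k` pJ per
parameter access, summed over layer shapes. These coefficients are
illustrative defaults expressing the standard scaling arguments (multiplier
energy roughly quadratic in operand width, access energy linear); they are
not calibrated silicon numbers, and only orderings and ratios between
models are meaningful or asserted. Explicit per-k tables can replace them.
One consequence worth stating: with fan-out routing, spiking energy grows
linearly in the horizon \(T\), so the ordering "spiking < 8-bit quantized"
holds at the pipeline's selected design point (T ≤ 200 here) and is a
default-parameter property, not a physical law; at \(T = 1000\) the routing
term alone can exceed the 8-bit model's cost.

## Metrics

Confusion counts, accuracy, precision, recall/sensitivity, F1, specificity
follow their standard closed forms; AUC integrates the empirical ROC of
continuous scores by the trapezoidal rule (cross-checked against pROC in
the tests). Metrics with zero denominators return `NaN` with a warning and
a flag rather than raising, so batch sweeps don't abort. Bland–Altman
agreement between two models' accuracies reports the mean, extreme values
and 1.96-sd limits of agreement of the paired differences.

## Problem sizes and determinism

The default pipeline simulates 600 s of recording (≈16,800 interrogations,
600 windows, 450 train / 150 test), trains for at most 100 epochs with
early stopping, evaluates quantization at k ∈ {2,4,8,16,32,64}, and sweeps
10 thresholds × 5 evaluation sizes (100–2000, resampled with replacement
from the test partition). These sizes keep a full run around one to two
minutes on a single core while leaving every comparison well resolved; all
stage seeds derive from one master seed, and a rerun with the same
configuration reproduces every artifact byte for byte.

## Known limitations

* The generator's realism gaps listed above; in particular, accuracies on
  this synthetic study sit at or near ceiling and should be read as
  pipeline validation, not clinical performance.
* Quantization-aware training is not implemented (post-training
  quantization only).
* Inter-spike-interval encoding is a documented stub; only rate coding is
  supported. Residual and concatenation conversion rules are out of scope
  (the canonical architecture uses neither).
* Hardware mapping (cluster decomposition, network-on-chip placement,
  cycle-accurate simulation) is out of scope; the energy model is
  per-event arithmetic, not a hardware simulator.
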