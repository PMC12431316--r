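---
title: "Methods: energy-aware spiking classification of fused ECG/PCG signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy-aware spiking classification of fused ECG/PCG signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spikecardio)
```

## The problem

Electrocardiogram (ECG) and phonocardiogram (PCG) signals describe the heart
from two complementary angles — electrical conduction and mechanical/acoustic
activity. Screening for cardiovascular disease benefits from using both, but
deep models that fuse them are usually conventional artificial neural
networks (ANNs), whose multiply–accumulate (MAC) workload makes them
expensive for wearable and edge hardware. `spikecardio` implements a
detection pipeline designed around that trade-off: spiking convolutional
networks (SCNNs) classify time–frequency images of the ECG and of a fused
ECG−PCG channel, a confidence-gated rule merges the two decisions, and the
package accounts for the spike activity and energy implied by every
inference.

The pipeline has four stages: sliding-window segmentation, time–frequency
transformation by adaptive superlets, per-modality spiking network training,
and decision-level fusion.

## Signal-level fusion: the EPCG channel

With both channels sampled synchronously, the fused channel is a point-wise
difference, `epcg = n(ecg) − n(pcg)` (`differential_fuse()`). Differencing
is chosen for two properties: it costs one subtraction per sample, and any
common-mode component — background noise picked up by both sensors on the
same clock — cancels exactly. The normalisation `n` is configurable:

* `zscore` (default): ECG amplitudes are mV-scale while PCG amplitudes are
  acoustic; z-scoring each segment first makes the difference balanced.
  Whether to normalise before differencing is genuinely open; the literal
  difference is available as `none`.
* `none`: the literal point-wise difference, with exact common-mode
  rejection and linearity (both are property-tested).

The difference order is fixed as ECG − PCG; magnitude spectrograms are
indifferent to the sign.

## The fractional adaptive superlet transform

A single Morlet wavelet trades time against frequency resolution through its
cycle count. Superlets sharpen both at once: at each frequency the
spectrogram row is the *geometric mean* of the responses of several wavelets
whose cycle counts are multiples `c1, 2·c1, …` of a base count. The number
of combined wavelets (the *order*) grows linearly with frequency
(`order_function()`):

    a(f) = o_min + (o_max − o_min) · (f − f_min) / (f_max − f_min)

so low frequencies keep good time resolution while high frequencies gain
frequency resolution, approximating constant absolute bandwidth across a
wideband analysis range. The *fractional* variant lets the order vary
continuously: for order `o = k + r` the first `k` wavelets enter with full
exponent and the `(k+1)`-th with exponent `r`, normalised by `o`:

    R = (R_1 · R_2 ··· R_k · R_{k+1}^r)^(1/o)

Continuity of `o → R` across integer boundaries (property-tested at
relative jump `< 1e-6` for an `1e-8` step) is what removes the banding
artifacts a discrete order schedule would produce. Each single-wavelet
response is `2·|x ∗ ψ|` with a unit-energy Gaussian envelope of standard
deviation `cycles / (5 f)`; convolutions are zero-padded FFT products, and
the wavelet bank is cached per signal length so thousands of equal-length
segments reuse one plan.

Parameters that matter:

* `f_min`, `f_max` — the analysed band. Full-scale default 1–250 Hz.
  **Support constraint:** the widest envelope must fit inside the analysed
  segment; on a 6-s window the near-DC superlets at 1 Hz (where the
  fractional ramp already engages a 2·c1-cycle wavelet) are wider than the
  window, and `aslt_transform()` refuses with a clear message. The pipeline
  therefore uses `f_min = 3` Hz for 6-s segments, and `f_max = 400` Hz so
  that the full murmur band (100–400 Hz) is inside the analysis range.
* `o_min`, `o_max` — order ramp endpoints (1 and 16 at full scale; 1 and 8
  in the desk-scale pipeline, where 64 × 64 output images cannot resolve the
  extra sharpness anyway).
* `n_freqs` — log-spaced rows (100 full-scale / 32 desk-scale). Log spacing
  matches the roughly geometric distribution of physiological bands (heart
  rate harmonics, QRS energy, S1/S2, murmur).

`render_image()` turns a spectrogram into the classifier's input: `log1p`
dynamic-range compression, bilinear resampling to a square, then min-max
normalisation to `[0, 1]` (normalising after the resample keeps the
0-and-1 extremes exact). Grayscale is deliberate — a single channel
preserves the ridge structure the classifier needs.

## The spiking convolutional network

The architecture (`scnn_config()`, `build_network()`):

* block 1: 7×7 convolution, stride 2, 1 → 32 channels; batchnorm;
  integrate-and-fire (IF) neurons; 2×2 max-pool;
* blocks 2–4: 3×3 convolutions, padding 1, doubling channels
  (→ 64 → 128 → 256), each with batchnorm + IF + 2×2 max-pool;
* flatten → fully connected 12,544 → 512 with IF → 512 → 2 with IF.

At 224 × 224 input the pre-flatten map is 256 × 7 × 7 — this arithmetic is
what pins the input size, the pool geometry (2×2, stride 2), and the hidden
width. 3- and 5-block variants are supported for depth ablations.

**Neuron model.** The IF neuron is leak-free: the membrane accumulates its
input, `V[t] − V[t−1] = X[t]`, fires when `V` reaches the threshold
(default 1.0), and hard-resets to 0 (`if_step()`; subtract-reset is
available). A continuous-time form of these dynamics with a *positive*
feedback term appears in some presentations; it contradicts the leak-free
discrete recurrence and is treated here as a typographical artifact — the
discrete recurrence is the implemented ground truth, verified against a
brute-force simulation.

**Temporal dimension.** A static input image is presented identically at
each of `T` time steps; the output class scores are the softmax of the mean
output-spike vector over the `T` steps (temporal mean pooling). The
full-scale default is `T = 6`, balancing validation loss against spike
rate; the desk-scale pipeline uses `T = 2`.

**Training.** The spike nonlinearity is non-differentiable; the backward
pass substitutes the arctangent surrogate
`g(x) = (1/π)·atan((π/2)·α·x) + 1/2` (derivative `α/2` at the threshold)
while the forward pass emits binary spikes. Backpropagation-through-time
runs over the `T` steps with the reset detached — the standard
surrogate-gradient recipe. The loss is cross-entropy on the temporally
pooled softmax (unstated in the source method; this is the conventional
choice consistent with softmax confidences at the fusion stage). Adam with
cosine-annealed learning rate; batchnorm statistics are shared across the
`T` steps by laying the batch out as `N·T` presentations.

Numerical/engineering choices worth recording:

* `α = 2` is the default surrogate slope (the convention of the framework
  family this model descends from). In the desk-scale regime — `T = 2`,
  six thresholding layers, a few hundred gradient steps — that surrogate
  is too narrow: units far from threshold receive almost no gradient and
  the output layer can stay permanently silent (the loss pins at
  `log 2`). The pipeline's smoke configuration therefore uses `α = 1`,
  whose wider tails keep gradient flowing; with it the EPCG branch trains
  to perfect held-out accuracy within five epochs.
* The full-scale initial learning rate 0.01 diverges at desk scale (small
  batches, small images); the smoke configuration uses 0.002.
* Weights are He-initialised; conv biases are redundant under batchnorm
  but kept for the plain layer contract.
* All exact-gradient primitives (conv im2col/GEMM, batchnorm, max-pool,
  fully connected) are verified against central finite differences.

## Confidence-based decision fusion

Two branches are trained — ECG (primary, "model 1") and EPCG — and fused
per segment (`cdd_fuse()`): if the primary model's confidence `max(p1)`
exceeds the threshold τ (default 0.5, strict comparison), its prediction is
accepted unchanged; otherwise the fused distribution is the normalised
weighted average `(w1·p1 + w2·p2)/(w1 + w2)` (equal weights by default).
Ties in the final argmax break toward the lower class index.

For binary softmax outputs `max(p1) ≥ 0.5` always, so with τ = 0.5 the
secondary model is consulted exactly when the primary is *maximally
uncertain* — including the degenerate case of a silent output layer, whose
temporal-mean softmax is exactly `[0.5, 0.5]`. The comparison mode
(`strict_greater` vs `greater_equal`) and the weights are exposed rather
than fixed, because the operational definition of "exceeds" at the boundary
is ambiguous in the source description and materially changes behaviour.
In the desk-scale smoke run this gating is visibly load-bearing: the ECG
branch (whose synthetic class cue, QRS widening, is subtler) often remains
uncertain, and the confident EPCG branch corrects it — the fused accuracy
then tracks the stronger branch.

## Spike-rate and energy accounting

Every spiking layer's activity is traced at inference. A layer's spike rate
is its total spike count over all time steps divided by its neuron count
(`layer_spike_rates()`); the overall rate pools all layers. A 2-neuron
output layer in which exactly one neuron fires per step yields, at `T = 6`,
a layer rate of 3.0 — a useful closed-form anchor.

The energy model (`energy_report()`, `count_ann_ops()`): the isomorphic ANN
executes one MAC per convolution/FC product (pooling and batchnorm are
excluded — the dominant-term convention); the SNN replaces MACs with
event-driven accumulates, so

    OP_SNN = spike_rate × OP_ANN

With 45 nm CMOS per-op energies (0.9 pJ add, 3.7 pJ multiply, 4.6 pJ MAC),
the ANN/SNN energy ratio is `4.6 / (rate × 0.9)` — about 5.1 at rate 1.0
and growing as activity gets sparser. The printed equation indexes the
spike rate per layer; applied arithmetic uses the overall rate, and the
package computes both so either convention can be reported.
`comparison_table()` performs the total-energy arithmetic for
cross-model comparisons (operation counts in millions × per-op energy).

## The synthetic data generator

Real paired recordings (e.g. the public heart-sound challenge corpora)
cannot ship with a package, so `generate_record()` synthesises structurally
faithful pairs:

* **ECG**: a quasi-periodic train of Gaussian P-QRS-T templates with
  beat-to-beat heart-rate jitter (default 70 ± 5 bpm at 2000 Hz);
* **PCG**: S1 wave packets aligned to each R peak and S2 packets at 35% of
  the RR interval (a plausible systole duration, fixed for
  reproducibility), both band-limited truncated-Gaussian bursts in the
  30–150 Hz range;
* **abnormal records** (+1): a mid-systolic murmur — white noise band-passed
  to 100–400 Hz, enveloped inside systole, scaled by `murmur_gain`
  (default 0.6) — plus QRS widening by a factor 1.4 on the ECG;
* independent Gaussian sensor noise (sd 0.05) on both channels.

Records default to 20.5 s (41,000 samples), deliberately above the
40,000-sample selection rule, so the preprocessing path (reject short
records, keep samples 4000–39,999, i.e. 36,000 points) is exercised
end-to-end. Random draws are consumed in a label-independent order, so the
normal/abnormal pair generated from one seed differs only in QRS width and
inside the systolic murmur windows — several invariance tests rely on this.

What the generator does *not* emulate: real murmur morphology and timing
variety, pathological ECG beyond QRS widening, sensor artifacts,
inter-subject variability, or class-dependent recording length. Passing
tests on this data demonstrates that the pipeline's machinery — selection,
segmentation without leakage, transform, training dynamics, fusion,
accounting — works and that the two synthetic classes are separable by
time–frequency features; it says nothing about clinical performance.

## Desk-scale study conditions

The test-suite smoke run and the examples use deliberately reduced problem
sizes so a single CPU completes them in minutes: 100 records, record-level
9:1 split stratified by label, 6-s windows with 2-s/6-s steps for
normal/abnormal, signals decimated to 1000 Hz before the transform,
32-frequency superlet grid (orders 1–8) over 3–400 Hz, 64 × 64 images,
`T = 2`, five epochs per branch at batch 16. Full-scale settings (224 × 224,
orders up to 16, `T = 6`, 150/160 epochs at lr 0.01) remain the documented
defaults of `aslt_config()`, `scnn_config()` and `train_config()`.

Splits and cross-validation folds are assigned at the *record* level before
any augmentation, so no segment of a held-out record ever reaches training —
with sliding-window augmentation, a segment-level split would leak nearly
identical windows across the boundary.

## Known limitations

* The sliding-window census of the original study's curated corpus cannot
  be reproduced from stated parameters alone, so published per-class sample
  counts are not a test surface here.
* At `T = 2` the output layer's temporal-mean rates take only three values
  per neuron; class probabilities are correspondingly coarse. This is a
  property of short-T spiking inference, not of the implementation.
* WFDB-format ingestion is out of scope (no WFDB reader in the supported
  dependency set); the CSV layout (`ecg,pcg` columns plus `REFERENCE.csv`)
  is the supported interchange format.
* Energy figures are operation-count models at fixed per-op CMOS costs;
  memory traffic and hardware-measured power are out of scope.
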