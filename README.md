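# spikecardio

Energy-aware detection of cardiovascular abnormalities from paired
electrocardiogram (ECG) and phonocardiogram (PCG) recordings, using spiking
convolutional neural networks (SCNNs).

ECG and PCG view the heart electrically and mechanically/acoustically; using
both improves screening, but conventional deep models pay for it in
multiply–accumulate (MAC) operations — a real constraint on wearables.
`spikecardio` implements a pipeline built around that trade-off:

1. **Signal-level fusion** — a fused channel `EPCG = n(ECG) − n(PCG)`
   (point-wise differencing of the synchronised channels; common-mode noise
   cancels exactly, at the cost of one subtraction per sample).
2. **Fractional adaptive superlet transform (FASLT)** — time–frequency
   images whose per-frequency order
   `a(f) = o_min + (o_max − o_min)(f − f_min)/(f_max − f_min)` geometrically
   combines `a(f)` Morlet wavelets (cycle counts `c1, 2c1, …`, fractional
   last exponent), giving near-constant absolute bandwidth across the band.
3. **Spiking classification** — two SCNN branches (ECG and EPCG), each
   four conv-batchnorm-IF-maxpool blocks (7×7/stride-2 stem to 32 channels,
   then 3×3 convs to 64/128/256) and a 12,544 → 512 → 2 spiking head.
   Integrate-and-fire neurons follow the leak-free recurrence
   `V[t] − V[t−1] = X[t]` with threshold 1 and hard reset; training uses
   backprop-through-time with the arctangent surrogate
   `g(x) = (1/π)atan((π/2)αx) + ½`. Static inputs are repeated `T` steps
   and output spikes are averaged (temporal mean pooling).
4. **Confidence-based decision fusion (CDD)** — accept the primary (ECG)
   branch when its confidence `max(p1)` exceeds τ (default 0.5); otherwise
   output the normalised weighted average of both branches.
5. **Spike/energy accounting** — per-layer spike rates
   (`spikes / neurons` over all time steps), SNN operation count
   `OP_SNN = rate × OP_ANN`, and 45 nm CMOS energy (0.9 pJ/add vs
   4.6 pJ/MAC), so every trained model reports the energy it would cost.

A synthetic paired-signal generator (Gaussian P-QRS-T trains; S1/S2 wave
packets; band-limited 100–400 Hz mid-systolic murmurs and QRS widening for
the abnormal class) makes the whole pipeline runnable and testable with no
clinical data.

## Worked example

```r
library(spikecardio)

cfg <- run_config(
  synth = synth_config(n_records = 100, seed = 11),  # 100 records, ~20.5 s each
  seed  = 5
)
res <- run_pipeline(cfg, verbose = TRUE)

print(res$fusion$metrics)
#> Acc 100.00%  Sen 100.00%  Spe 100.00%  F1 100.00%  AUC 100.00%
res$fusion$usage_fraction
#> [1] 0.3913043
res$branches$epcg$history$train_loss
#> [1] 0.7423 0.6510 0.4823 0.3666 0.3133
print(res$branches$epcg$energy)
#> ANN: 17.3M MAC = 79.7 uJ | SNN: rate 0.42 -> 7.2M ACC = 6.5 uJ | ANN/SNN 12.3x
```

This desk-scale run (~5 min on one CPU) generates 100 synthetic records,
rejects/trims them by the 40,000-sample rule, splits 9:1 at the record
level, segments with 6-s windows (2-s step for normal, 6-s for abnormal
records), renders 64×64 superlet images over 3–400 Hz, trains the two
branches (`T = 2`, 5 epochs, lr 0.002, surrogate slope α = 1), fuses
decisions at τ = 0.5, and reports metrics plus energy. The fused accuracy
of 100% on the cleanly separable synthetic classes shows the machinery
works end to end; the `usage_fraction` says the EPCG branch was consulted
for 39% of the test segments — exactly the segments where the ECG branch
was maximally uncertain. The energy line reads: at an overall spike rate
of 0.42, the spiking branch needs 7.2M accumulates (6.5 μJ) where the
isomorphic conventional network needs 17.3M MACs (79.7 μJ).

Full-scale settings — 224×224 images (pre-flatten map 256×7×7), superlet
orders up to 16, `T = 6`, 150/160 epochs at lr 0.01 — are the documented
defaults of `aslt_config()`, `scnn_config()` and `train_config()`.

A thin command-line wrapper ships at `inst/cli/spikecardio.R`
(`simulate`, `run`, `energy` subcommands over the same functions).

## Package layout

| | |
|---|---|
| `R/synth.R` | synthetic paired ECG/PCG generator |
| `R/signal_io.R` | CSV dataset I/O, selection/trimming, segmentation, record-level splits |
| `R/fusion_signal.R` | differential (EPCG) fusion |
| `R/aslt.R` | fractional adaptive superlet transform and image rendering |
| `R/nn_layers.R`, `R/scnn.R` | exact-gradient layer primitives; IF dynamics, surrogate gradients, training |
| `R/fusion_decision.R` | confidence-based decision fusion |
| `R/metrics.R`, `R/energy.R` | classification metrics; spike-rate and CMOS energy accounting |
| `R/pipeline.R` | `run_config()` / `run_pipeline()` orchestration |
| `vignettes/methods.Rmd` | the model, its assumptions, and every tunable that matters |
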