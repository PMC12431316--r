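# Desk-scale smoke configuration for the spikecardio CLI.
# Rscript inst/cli/spikecardio.R run --config inst/extdata/smoke.yaml --out runs/smoke
synth:
  n_records: 100
  duration: 20.5
  p_abnormal: 0.5
  heart_rate_bpm: 70
  heart_rate_sd: 5
  noise_sd: 0.05
  murmur_gain: 0.6
  seed: 11
net:
  in_size: 64
  T_steps: 2
  alpha: 1
aslt:
  f_min: 3
  f_max: 400
  n_freqs: 32
  o_min: 1
  o_max: 8
  fs: 1000
train:
  lr: 0.002
  epochs: 5
downsample_to: 1000
image_size: 64
test_fraction: 0.1
n_folds: 5
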