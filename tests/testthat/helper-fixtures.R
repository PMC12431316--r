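# Small shared fixtures, generated in code.

# A fast generator config for tests that need real records but not the full
# 20.5 s study-length signal.
quick_synth <- function(duration = 18, noise_sd = 0.02, murmur_gain = 0.6,
                        n_records = 8, seed = 101L, ...) {
  synth_config(duration = duration, noise_sd = noise_sd,
               murmur_gain = murmur_gain, n_records = n_records,
               seed = seed, ...)
}

# Band power of a signal between lo and hi Hz (periodogram sum).
band_power <- function(x, fs, lo, hi) {
  s <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  sum(s[f >= lo & f <= hi])
}

# Indices of local maxima of a vector (interior strict maxima).
local_maxima <- function(v) {
  n <- length(v)
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# A tiny recording with prescribed channel contents for I/O tests.
toy_recording <- function(n = 50000, fs = 2000, label = -1L, id = "toy") {
  structure(list(record_id = id, ecg = as.numeric(seq_len(n)),
                 pcg = -as.numeric(seq_len(n)), fs = fs,
                 label = as.integer(label)),
            class = "recording")
}
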