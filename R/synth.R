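#' Configuration for the synthetic paired ECG/PCG generator
#'
#' The generator emulates the structure of simultaneously recorded
#' electrocardiogram and phonocardiogram channels: one labelled record is a
#' pair of equal-length waveforms sampled at `sampling_rate`.  Normal records
#' carry a quasi-periodic P-QRS-T electrical template and S1/S2 heart-sound
#' bursts; abnormal records additionally carry a mid-systolic murmur band on
#' the PCG and a widened QRS complex on the ECG, so the two classes are
#' separable by time-frequency features.
#'
#' @param sampling_rate sampling frequency in Hz (default 2000).
#' @param duration record length in seconds.  The default 20.5 s yields
#'   41,000 samples, comfortably above the 40,000-sample selection rule the
#'   preprocessing stage applies.
#' @param n_records number of records a dataset should contain.
#' @param p_abnormal probability that a record is labelled abnormal.
#' @param heart_rate_bpm mean heart rate in beats per minute.
#' @param heart_rate_sd beat-to-beat heart-rate standard deviation (bpm);
#'   0 gives a perfectly regular rhythm.
#' @param noise_sd standard deviation of the additive Gaussian sensor noise
#'   applied to both channels (amplitude units).
#' @param murmur_gain amplitude scale of the 100-400 Hz mid-systolic murmur
#'   added to abnormal PCG channels; 0 disables the murmur.
#' @param qrs_widen multiplicative widening of the Q/R/S wave durations for
#'   abnormal ECG morphology (1 = no widening).
#' @param seed integer seed controlling dataset-level randomness.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(sampling_rate = 2000,
                         duration = 20.5,
                         n_records = 60,
                         p_abnormal = 0.5,
                         heart_rate_bpm = 70,
                         heart_rate_sd = 5,
                         noise_sd = 0.05,
                         murmur_gain = 0.6,
                         qrs_widen = 1.4,
                         seed = 1L) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop_invalid("sampling_rate must be > 0 (got %s)", format(sampling_rate))
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop_invalid("duration must be > 0 (got %s)", format(duration))
  }
  if (p_abnormal < 0 || p_abnormal > 1) {
    stop_invalid("p_abnormal must lie in [0, 1]")
  }
  if (heart_rate_bpm <= 0 || heart_rate_sd < 0) {
    stop_invalid("heart_rate_bpm must be > 0 and heart_rate_sd >= 0")
  }
  if (murmur_gain < 0 || noise_sd < 0) {
    stop_invalid("noise_sd and murmur_gain must be >= 0")
  }
  if (qrs_widen <= 0) stop_invalid("qrs_widen must be > 0")
  structure(list(
    sampling_rate = sampling_rate, duration = duration,
    n_records = as.integer(n_records), p_abnormal = p_abnormal,
    heart_rate_bpm = heart_rate_bpm, heart_rate_sd = heart_rate_sd,
    noise_sd = noise_sd, murmur_gain = murmur_gain,
    qrs_widen = qrs_widen, seed = as.integer(seed)
  ), class = "synth_config")
}

# P-QRS-T wave dictionary: per-wave time offset from the R peak (s),
# amplitude (arbitrary mV-like units) and Gaussian width (s).
ecg_wave_table <- function(qrs_widen = 1) {
  data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    offset = c(-0.20, -0.030, 0.0, 0.030, 0.30),
    amp    = c(0.12, -0.10, 1.0, -0.20, 0.28),
    sd     = c(0.025, 0.010 * qrs_widen, 0.012 * qrs_widen,
               0.010 * qrs_widen, 0.055)
  )
}

# Heart-sound burst parameters: S1 aligned to the R peak, S2 at 35% of the
# RR interval (a physiologically plausible systole, fixed for
# reproducibility).  Packets are truncated Gaussians times a sinusoidal
# carrier; outside +-4 sd the packet is exactly zero.
S1_SIGMA <- 0.020; S1_FREQ <- 60;  S1_AMP <- 0.9
S2_SIGMA <- 0.015; S2_FREQ <- 95;  S2_AMP <- 0.7
S2_FRACTION <- 0.35
PACKET_CUT <- 4        # truncation, in packet sds
MURMUR_CENTER <- 0.175 # murmur envelope centre, fraction of RR
MURMUR_SIGMA <- 0.04   # murmur envelope sd, fraction of RR
MURMUR_CUT <- 3        # murmur truncation, in envelope sds
MURMUR_BAND <- c(100, 400) # Hz

# Add a truncated Gaussian-envelope burst in place.
add_packet <- function(x, t, center, sigma, freq, amp, cut = PACKET_CUT) {
  idx <- which(abs(t - center) <= cut * sigma)
  if (length(idx)) {
    tau <- t[idx] - center
    x[idx] <- x[idx] + amp * exp(-tau^2 / (2 * sigma^2)) * sin(2 * pi * freq * tau)
  }
  x
}

# Band-limited murmur carrier: white noise passed through a Butterworth
# band-pass over MURMUR_BAND.
murmur_carrier <- function(n, fs) {
  w <- stats::rnorm(n)
  ny <- fs / 2
  hi <- min(MURMUR_BAND[2], 0.95 * ny)
  bf <- signal::butter(4, c(MURMUR_BAND[1], hi) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, w))
}

#' Generate one synthetic paired ECG/PCG recording
#'
#' ECG is a train of Gaussian P-QRS-T templates with beat-to-beat heart-rate
#' jitter; PCG places S1 bursts at each R peak and S2 bursts at 35% of the
#' RR interval.  Abnormal records (`label = +1`) add a noise-modulated
#' 100-400 Hz mid-systolic murmur scaled by `cfg$murmur_gain` and widen the
#' QRS waves by `cfg$qrs_widen`.  Both channels receive independent additive
#' Gaussian noise with sd `cfg$noise_sd`.  The random draws (heart-rate
#' jitter, channel noise, murmur carrier) are consumed in a fixed order that
#' does not depend on the label, so the normal/abnormal pair generated from
#' one seed differs only in QRS width and the systolic murmur windows.
#'
#' @param cfg a [synth_config()].
#' @param label class label, -1 (normal) or +1 (abnormal).
#' @param rng_seed integer seed; the record is a deterministic function of
#'   `(cfg, label, rng_seed)`.
#' @param record_id identifier stored on the record.
#' @return a `recording`: list with `record_id`, `ecg`, `pcg`, `fs`, `label`.
#' @export
generate_record <- function(cfg, label, rng_seed, record_id = "rec") {
  stopifnot(inherits(cfg, "synth_config"))
  if (!label %in% c(-1, 1)) stop_invalid("label must be -1 or +1")
  fs <- cfg$sampling_rate
  n <- round(cfg$duration * fs)
  t <- (seq_len(n) - 1) / fs

  with_seed(rng_seed, {
    # beat schedule: first R peak at half the first RR interval
    r_times <- numeric(0)
    rr <- numeric(0)
    tcur <- NA_real_
    repeat {
      hr <- stats::rnorm(1, cfg$heart_rate_bpm, cfg$heart_rate_sd)
      hr <- max(hr, 20)
      rri <- 60 / hr
      if (is.na(tcur)) tcur <- 0.5 * rri
      if (tcur >= cfg$duration) break
      r_times <- c(r_times, tcur)
      rr <- c(rr, rri)
      tcur <- tcur + rri
    }

    widen <- if (label > 0) cfg$qrs_widen else 1
    waves <- ecg_wave_table(widen)
    ecg <- numeric(n)
    for (k in seq_along(r_times)) {
      for (w in seq_len(nrow(waves))) {
        c0 <- r_times[k] + waves$offset[w]
        sd0 <- waves$sd[w]
        idx <- which(abs(t - c0) <= 5 * sd0)
        if (length(idx)) {
          ecg[idx] <- ecg[idx] +
            waves$amp[w] * exp(-(t[idx] - c0)^2 / (2 * sd0^2))
        }
      }
    }

    pcg <- numeric(n)
    for (k in seq_along(r_times)) {
      pcg <- add_packet(pcg, t, r_times[k], S1_SIGMA, S1_FREQ, S1_AMP)
      pcg <- add_packet(pcg, t, r_times[k] + S2_FRACTION * rr[k],
                        S2_SIGMA, S2_FREQ, S2_AMP)
    }

    # fixed draw order: ECG noise, PCG noise, murmur carrier (always drawn)
    ecg_noise <- stats::rnorm(n, sd = 1)
    pcg_noise <- stats::rnorm(n, sd = 1)
    carrier <- murmur_carrier(n, fs)

    if (label > 0 && cfg$murmur_gain > 0) {
      env <- numeric(n)
      for (k in seq_along(r_times)) {
        c0 <- r_times[k] + MURMUR_CENTER * rr[k]
        s0 <- MURMUR_SIGMA * rr[k]
        idx <- which(abs(t - c0) <= MURMUR_CUT * s0)
        if (length(idx)) {
          env[idx] <- pmax(env[idx], exp(-(t[idx] - c0)^2 / (2 * s0^2)))
        }
      }
      pcg <- pcg + cfg$murmur_gain * env * carrier
    }

    ecg <- ecg + cfg$noise_sd * ecg_noise
    pcg <- pcg + cfg$noise_sd * pcg_noise

    structure(list(record_id = record_id, ecg = ecg, pcg = pcg,
                   fs = fs, label = as.integer(label)),
              class = "recording")
  })
}

#' Systolic murmur windows of a recording configuration
#'
#' Returns the sample-index windows (1-based, inclusive) in which the murmur
#' envelope of an abnormal record generated with the same `(cfg, rng_seed)`
#' is non-zero.  Used by tests to verify that the murmur modifies the PCG
#' only inside systole.
#'
#' @inheritParams generate_record
#' @return integer vector of sample indices inside systolic murmur windows.
#' @export
murmur_windows <- function(cfg, rng_seed) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$sampling_rate
  n <- round(cfg$duration * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(rng_seed, {
    r_times <- numeric(0); rr <- numeric(0); tcur <- NA_real_
    repeat {
      hr <- max(stats::rnorm(1, cfg$heart_rate_bpm, cfg$heart_rate_sd), 20)
      rri <- 60 / hr
      if (is.na(tcur)) tcur <- 0.5 * rri
      if (tcur >= cfg$duration) break
      r_times <- c(r_times, tcur); rr <- c(rr, rri)
      tcur <- tcur + rri
    }
    idx <- integer(0)
    for (k in seq_along(r_times)) {
      c0 <- r_times[k] + MURMUR_CENTER * rr[k]
      s0 <- MURMUR_SIGMA * rr[k]
      idx <- c(idx, which(abs(t - c0) <= MURMUR_CUT * s0))
    }
    sort(unique(idx))
  })
}

#' Simple R-peak picker
#'
#' Local-maximum detector with an amplitude floor (fraction of the channel
#' maximum) and a refractory distance.  Adequate for the clean synthetic ECG
#' morphology; not a clinical QRS detector.
#'
#' @param x numeric ECG sequence.
#' @param fs sampling rate in Hz.
#' @param min_height_frac amplitude floor relative to `max(x)`.
#' @param min_dist_s refractory period in seconds.
#' @return integer sample indices (1-based) of detected R peaks.
#' @export
find_r_peaks <- function(x, fs, min_height_frac = 0.5, min_dist_s = 0.25) {
  n <- length(x)
  if (n < 3) return(integer(0))
  thr <- min_height_frac * max(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= thr]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-x[cand])]
  keep <- integer(0)
  min_dist <- min_dist_s * fs
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Generate a labelled synthetic dataset
#'
#' Draws `cfg$n_records` records whose labels are Bernoulli(`cfg$p_abnormal`)
#' in {-1, +1}; per-record seeds are derived from `cfg$seed` so the dataset
#' is reproducible as a whole.
#'
#' @param cfg a [synth_config()].
#' @return list of `recording` objects with unique `record_id`s.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_records <= 0) stop_invalid("n_records must be > 0")
  with_seed(cfg$seed, {
    labels <- ifelse(stats::runif(cfg$n_records) < cfg$p_abnormal, 1L, -1L)
    seeds <- vapply(seq_len(cfg$n_records),
                    function(i) derive_seed(cfg$seed, i), integer(1))
    lapply(seq_len(cfg$n_records), function(i) {
      generate_record(cfg, labels[i], seeds[i],
                      record_id = sprintf("s%04d", i))
    })
  })
}

#' Write a dataset in the two-column CSV layout
#'
#' Each record becomes `<record_id>.csv` with columns `ecg,pcg`, plus a
#' `REFERENCE.csv` of `record_id,label` mirroring the PhysioNet challenge
#' layout.
#'
#' @param records list of `recording` objects.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in records) {
    data.table::fwrite(data.table::data.table(ecg = rec$ecg, pcg = rec$pcg),
                       file.path(dir, paste0(rec$record_id, ".csv")))
  }
  ref <- data.table::data.table(
    record_id = vapply(records, `[[`, "", "record_id"),
    label = vapply(records, `[[`, integer(1), "label")
  )
  data.table::fwrite(ref, file.path(dir, "REFERENCE.csv"))
  invisible(dir)
}
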