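#' Configuration for signal-level differential fusion
#'
#' @param normalize_before per-segment normalisation applied to each channel
#'   before differencing: `"zscore"` (default; ECG is mV-scale while PCG is
#'   acoustic, so raw units are not commensurate), `"minmax"`, or `"none"`
#'   (the literal point-wise difference).
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(normalize_before = c("zscore", "minmax", "none")) {
  normalize_before <- match.arg(normalize_before)
  structure(list(normalize_before = normalize_before, order = "ecg_minus_pcg"),
            class = "fusion_config")
}

normalize_channel <- function(x, mode) {
  switch(mode,
    none = x,
    zscore = {
      s <- stats::sd(x)
      if (!is.finite(s) || s < .Machine$double.eps) x - mean(x)
      else (x - mean(x)) / s
    },
    minmax = {
      r <- range(x)
      if (diff(r) < .Machine$double.eps) x - r[1]
      else (x - r[1]) / diff(r)
    }
  )
}

#' Differential signal-level fusion (EPCG)
#'
#' Constructs the fused EPCG channel by point-wise differencing of the
#' synchronously sampled ECG and PCG: `epcg[i] = n(ecg)[i] - n(pcg)[i]`,
#' where `n` is the configured per-segment normalisation.  With
#' normalisation off the operation is linear and rejects any common-mode
#' component added to both channels, which is the rationale for fusing by
#' differencing: synchronous background noise cancels.
#'
#' @param ecg,pcg equal-length numeric sequences sampled on the same clock.
#' @param cfg a [fusion_config()].
#' @return numeric EPCG sequence of the same length.
#' @export
differential_fuse <- function(ecg, pcg, cfg = fusion_config()) {
  if (length(ecg) != length(pcg)) {
    stop_invalid("ECG and PCG lengths differ (%d vs %d): channels must be aligned",
                 length(ecg), length(pcg))
  }
  normalize_channel(ecg, cfg$normalize_before) -
    normalize_channel(pcg, cfg$normalize_before)
}
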