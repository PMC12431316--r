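#' Configuration of the (fractional) adaptive superlet transform
#'
#' The adaptive superlet transform estimates a time-frequency
#' representation by geometrically combining the responses of a set of
#' Morlet wavelets per frequency.  The number of combined wavelets (the
#' order) grows linearly with frequency between `o_min` at `f_min` and
#' `o_max` at `f_max`, trading time resolution at low frequencies for
#' frequency resolution at high frequencies at roughly constant absolute
#' bandwidth.  With `fractional = TRUE` the order varies continuously: the
#' last wavelet enters the geometric mean with a fractional exponent, which
#' removes the banding that discrete order jumps would otherwise imprint on
#' the spectrogram.
#'
#' @param f_min,f_max analysed frequency range in Hz (`f_max` at most the
#'   Nyquist frequency `fs/2`).
#' @param n_freqs number of frequency rows, log-spaced from `f_min` to
#'   `f_max`.
#' @param o_min,o_max superlet order at `f_min` / `f_max` (real, >= 1).
#' @param c1 cycle count of the base wavelet; the i-th wavelet of a superlet
#'   uses `i * c1` cycles.
#' @param fs sampling rate of the analysed signal in Hz.
#' @param fractional use the fractional (continuous-order) variant
#'   (default) or round orders to integers.
#' @return an `aslt_config` list.
#' @export
aslt_config <- function(f_min = 1, f_max = 250, n_freqs = 100,
                        o_min = 1, o_max = 16, c1 = 3,
                        fs = 2000, fractional = TRUE) {
  if (!(f_min > 0 && f_max > f_min)) stop_invalid("need 0 < f_min < f_max")
  if (f_max > fs / 2) stop_invalid("f_max (%g) above Nyquist (%g)", f_max, fs / 2)
  if (o_min > o_max || o_min < 1) stop_invalid("need 1 <= o_min <= o_max")
  if (c1 < 1) stop_invalid("c1 must be >= 1")
  if (n_freqs < 2) stop_invalid("n_freqs must be >= 2")
  structure(list(f_min = f_min, f_max = f_max, n_freqs = as.integer(n_freqs),
                 o_min = o_min, o_max = o_max, c1 = c1, fs = fs,
                 fractional = isTRUE(fractional)),
            class = "aslt_config")
}

# Morlet envelope convention: Gaussian sd sigma_t = cycles / (K_SD * f),
# i.e. `cycles` periods span K_SD standard deviations of the envelope.
K_SD <- 5
WAVELET_SUPPORT_SD <- 5 # wavelet truncated at +- this many envelope sds

#' Frequency-dependent superlet order
#'
#' Linear ramp `a(f) = o_min + (o_max - o_min) * (f - f_min) / (f_max -
#' f_min)`, clamped to `[o_min, o_max]` outside the analysed range.
#'
#' @param f frequency (Hz), vectorised.
#' @param cfg an [aslt_config()].
#' @return order(s), same length as `f`.
#' @export
order_function <- function(f, cfg) {
  if (cfg$f_max == cfg$f_min) stop_invalid("f_max must differ from f_min")
  a <- cfg$o_min + (cfg$o_max - cfg$o_min) * (f - cfg$f_min) / (cfg$f_max - cfg$f_min)
  pmin(pmax(a, cfg$o_min), cfg$o_max)
}

# Complex Morlet wavelet sampled at fs, unit-energy envelope, truncated at
# +- WAVELET_SUPPORT_SD sds.  Returns the complex tap vector (odd length).
morlet_taps <- function(f, cycles, fs) {
  sigma_t <- cycles / (K_SD * f)
  half <- max(1L, ceiling(WAVELET_SUPPORT_SD * sigma_t * fs))
  tau <- (-half:half) / fs
  env <- exp(-tau^2 / (2 * sigma_t^2))
  env <- env / sqrt(sum(env^2) / fs) # unit energy in continuous-time units
  env * exp(1i * 2 * pi * f * tau)
}

# FFT-based "same" linear convolution of a real signal with complex taps.
# Returns the complex response aligned with x.  `Xf` may carry a
# precomputed fft of the zero-padded signal (length nfft).
convolve_same <- function(x, taps, Xf = NULL, nfft = NULL) {
  n <- length(x)
  m <- length(taps)
  if (is.null(nfft)) nfft <- stats::nextn(n + m - 1, 2)
  if (is.null(Xf)) Xf <- stats::fft(c(x, numeric(nfft - n)))
  Hf <- stats::fft(c(taps, complex(nfft - m)))
  full <- stats::fft(Xf * Hf, inverse = TRUE) / nfft
  lag <- (m - 1) / 2 # taps have odd length, centre tap at lag 0
  full[(lag + 1):(lag + n)]
}

#' Single-wavelet (Morlet) magnitude response
#'
#' `2 * |x (*) psi_{f, cycles}|` in "same"-length complex convolution, the
#' amplitude-scaled magnitude response of one Morlet wavelet.
#'
#' @param x real signal.
#' @param f centre frequency in Hz.
#' @param cycles number of cycles of the wavelet (>= 1).
#' @param fs sampling rate in Hz.
#' @return non-negative response, same length as `x`.
#' @export
morlet_response <- function(x, f, cycles, fs) {
  if (f <= 0 || f > fs / 2) stop_invalid("f must be in (0, fs/2]")
  if (cycles < 1) stop_invalid("cycles must be >= 1")
  2 * Mod(convolve_same(x, morlet_taps(f, cycles, fs)))
}

# Internal superlet kernel on precomputed wavelet responses.
# responses: list of non-negative response vectors for cycles i*c1,
# i = 1..n_wavelets; weights: exponents per response; order: normaliser.
combine_geometric <- function(responses, weights, order) {
  acc <- numeric(length(responses[[1]]))
  for (i in seq_along(responses)) {
    acc <- acc + weights[i] * log(responses[[i]])
  }
  out <- exp(acc / order)
  out[!is.finite(out)] <- 0 # log(0) = -Inf propagates to a zero response
  out
}

superlet_weights <- function(order, fractional) {
  if (order < 1) stop_invalid("order must be >= 1")
  if (!fractional) order <- max(1, round(order))
  k <- floor(order)
  r <- order - k
  if (r > 0) list(weights = c(rep(1, k), r), order = order)
  else list(weights = rep(1, k), order = order)
}

#' Superlet magnitude response at one frequency
#'
#' Geometric mean of the responses of wavelets with cycle counts `i * c1`,
#' `i = 1..floor(order)`; a fractional remainder `r = order - floor(order)`
#' contributes the next wavelet with exponent `r`, and the total exponent is
#' normalised by `order`:
#' `R = (prod_i R_i * R_{k+1}^r)^(1/order)`.
#' At `order = 1` this reduces to a single Morlet response; the map
#' `order -> R` is continuous across integer boundaries, which is the point
#' of the fractional formulation.
#'
#' @param x real signal.
#' @param f centre frequency in Hz.
#' @param order real superlet order (>= 1).
#' @param cfg an [aslt_config()] supplying `c1`, `fs` and the
#'   integer/fractional mode.
#' @return non-negative response, same length as `x`.
#' @export
superlet_response <- function(x, f, order, cfg) {
  w <- superlet_weights(order, cfg$fractional)
  responses <- lapply(seq_along(w$weights), function(i) {
    morlet_response(x, f, i * cfg$c1, cfg$fs)
  })
  combine_geometric(responses, w$weights, w$order)
}

# Cache of wavelet frequency responses keyed by (signal length, config).
.aslt_cache <- new.env(parent = emptyenv())

aslt_plan <- function(n, cfg) {
  key <- paste(n, cfg$f_min, cfg$f_max, cfg$n_freqs, cfg$o_min, cfg$o_max,
               cfg$c1, cfg$fs, cfg$fractional, sep = "|")
  if (!is.null(.aslt_cache[[key]])) return(.aslt_cache[[key]])
  freqs <- exp(seq(log(cfg$f_min), log(cfg$f_max), length.out = cfg$n_freqs))
  orders <- order_function(freqs, cfg)
  max_taps <- 0L
  rows <- lapply(seq_along(freqs), function(j) {
    w <- superlet_weights(orders[j], cfg$fractional)
    taps <- lapply(seq_along(w$weights), function(i) {
      morlet_taps(freqs[j], i * cfg$c1, cfg$fs)
    })
    list(weights = w$weights, order = w$order, taps = taps)
  })
  for (r in rows) for (tp in r$taps) max_taps <- max(max_taps, length(tp))
  nfft <- stats::nextn(n + max_taps - 1, 2)
  for (j in seq_along(rows)) {
    rows[[j]]$H <- lapply(rows[[j]]$taps, function(tp) {
      list(H = stats::fft(c(tp, complex(nfft - length(tp)))),
           lag = (length(tp) - 1) / 2)
    })
    rows[[j]]$taps <- NULL
  }
  plan <- list(freqs = freqs, orders = orders, rows = rows,
               nfft = nfft, max_taps = max_taps)
  .aslt_cache[[key]] <- plan
  plan
}

#' Adaptive superlet spectrogram of a signal
#'
#' One row per frequency on a log-spaced grid from `f_min` to `f_max`, each
#' row the superlet response at the frequency-dependent order `a(f)`
#' ([order_function()]): few wavelets (good time resolution) at low
#' frequencies, many (good frequency resolution) at high frequencies.
#' Convolutions are zero-padded FFT products; wavelet banks are cached per
#' `(length(x), cfg)`, so transforming many equal-length segments reuses one
#' plan.
#'
#' @param x real signal.
#' @param cfg an [aslt_config()].
#' @param source_channel provenance tag stored on the result
#'   (`"ECG"`, `"PCG"`, `"EPCG"`, ...).
#' @return a `spectrogram`: list with `values` (`n_freqs` x `length(x)`
#'   non-negative matrix), `freqs` (Hz), `times` (s), `source_channel`.
#' @export
aslt_transform <- function(x, cfg, source_channel = "ECG") {
  n <- length(x)
  plan <- aslt_plan(n, cfg)
  if (n < plan$max_taps) {
    stop_invalid("signal (%d samples) shorter than the widest wavelet (%d taps); %s",
                 n, plan$max_taps, "lower o_max/c1 or raise f_min")
  }
  Xf <- stats::fft(c(x, numeric(plan$nfft - n)))
  vals <- matrix(0, nrow = cfg$n_freqs, ncol = n)
  for (j in seq_along(plan$rows)) {
    row <- plan$rows[[j]]
    responses <- lapply(row$H, function(h) {
      full <- stats::fft(Xf * h$H, inverse = TRUE) / plan$nfft
      2 * Mod(full[(h$lag + 1):(h$lag + n)])
    })
    vals[j, ] <- combine_geometric(responses, row$weights, row$order)
  }
  structure(list(values = vals, freqs = plan$freqs,
                 times = (seq_len(n) - 1) / cfg$fs,
                 source_channel = source_channel),
            class = "spectrogram")
}

# Bilinear resample of a matrix to h_out x w_out (pixel-centre aligned).
resize_bilinear <- function(m, h_out, w_out) {
  h <- nrow(m); w <- ncol(m)
  map <- function(n_in, n_out) {
    x <- ((seq_len(n_out) - 0.5) * n_in / n_out) + 0.5 - 1 # 0-based coord
    pmin(pmax(x, 0), n_in - 1)
  }
  yi <- map(h, h_out); xi <- map(w, w_out)
  y0 <- pmin(floor(yi), h - 1); y1 <- pmin(y0 + 1, h - 1); wy <- yi - y0
  x0 <- pmin(floor(xi), w - 1); x1 <- pmin(x0 + 1, w - 1); wx <- xi - x0
  # interpolate rows then columns
  top <- m[y0 + 1, , drop = FALSE] * (1 - wy) + m[y1 + 1, , drop = FALSE] * wy
  out <- top[, x0 + 1, drop = FALSE] *
    matrix(1 - wx, h_out, w_out, byrow = TRUE) +
    top[, x1 + 1, drop = FALSE] * matrix(wx, h_out, w_out, byrow = TRUE)
  out
}

#' Render a spectrogram as a fixed-size grayscale image
#'
#' Compresses the dynamic range (`log1p` by default), bilinearly resamples
#' to `size x size`, and min-max normalises to `[0, 1]` — the
#' single-channel input format the spiking classifier consumes.  A constant
#' (e.g. all-zero) spectrogram maps to an all-zero image rather than
#' dividing by zero.
#'
#' @param s a `spectrogram`.
#' @param size output side length in pixels (default 224).
#' @param scale `"log1p"` (default) or `"linear"`.
#' @return a `spectro_image`: `size` x `size` matrix in `[0, 1]` with a
#'   `provenance` attribute.
#' @export
render_image <- function(s, size = 224, scale = c("log1p", "linear")) {
  scale <- match.arg(scale)
  stopifnot(inherits(s, "spectrogram"))
  v <- s$values
  if (!length(v)) stop_invalid("empty spectrogram")
  if (scale == "log1p") v <- log1p(v)
  out <- resize_bilinear(v, size, size)
  rng <- range(out)
  out <- if (diff(rng) < .Machine$double.eps) {
    matrix(0, size, size)
  } else {
    (out - rng[1]) / diff(rng)
  }
  structure(out, class = c("spectro_image", "matrix"),
            provenance = s$source_channel)
}
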