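test_that("order ramp hits its endpoints and midpoint for random configs", {
  set.seed(10)
  for (i in 1:20) {
    f_min <- runif(1, 0.5, 20)
    f_max <- f_min + runif(1, 10, 200)
    o_min <- runif(1, 1, 4)
    o_max <- o_min + runif(1, 0, 20)
    cfg <- aslt_config(f_min, f_max, n_freqs = 10, o_min = o_min,
                       o_max = o_max, fs = 2 * f_max + 10)
    expect_equal(order_function(f_min, cfg), o_min)
    expect_equal(order_function(f_max, cfg), o_max)
    expect_equal(order_function((f_min + f_max) / 2, cfg),
                 (o_min + o_max) / 2)
    # clamping outside the analysed range
    expect_equal(order_function(f_min - 1, cfg), o_min)
    expect_equal(order_function(f_max + 50, cfg), o_max)
  }
})

test_that("Morlet response to a pure tone has a flat interior plateau", {
  fs <- 500
  t <- (0:1499) / fs
  x <- cos(2 * pi * 40 * t)
  r <- morlet_response(x, 40, 3, fs)
  interior <- r[300:1200]
  expect_lt((max(interior) - min(interior)) / mean(interior), 0.01)
  expect_equal(morlet_response(numeric(800), 40, 3, fs), numeric(800))
})

test_that("doubling cycles narrows the frequency response", {
  fs <- 500
  t <- (0:1999) / fs
  on_tone <- cos(2 * pi * 40 * t)
  off_tone <- cos(2 * pi * 55 * t)
  # leakage of an off-target tone relative to the on-target response:
  # more cycles = narrower bandwidth = strictly less relative leakage
  leak <- function(cycles) {
    mean(morlet_response(off_tone, 40, cycles, fs)[500:1500]) /
      mean(morlet_response(on_tone, 40, cycles, fs)[500:1500])
  }
  expect_lt(leak(6), leak(3))
  expect_lt(leak(12), leak(6))
})

test_that("superlet response reduces to Morlet at order 1 and handles zeros", {
  fs <- 500
  cfg <- aslt_config(5, 100, n_freqs = 10, o_min = 1, o_max = 5, c1 = 3,
                     fs = fs)
  t <- (0:1499) / fs
  x <- cos(2 * pi * 40 * t)
  expect_equal(superlet_response(x, 40, 1, cfg),
               morlet_response(x, 40, 3, fs))
  expect_equal(superlet_response(numeric(600), 40, 2, cfg), numeric(600))
  expect_error(superlet_response(x, 40, 0.5, cfg), "order")
})

test_that("geometric mean lies between the min and max factor responses", {
  fs <- 500
  cfg <- aslt_config(5, 100, n_freqs = 10, o_min = 1, o_max = 5, c1 = 3,
                     fs = fs)
  set.seed(3)
  x <- rnorm(1200)
  r <- superlet_response(x, 30, 3, cfg)
  f1 <- morlet_response(x, 30, 3, fs)
  f2 <- morlet_response(x, 30, 6, fs)
  f3 <- morlet_response(x, 30, 9, fs)
  lo <- pmin(f1, f2, f3); hi <- pmax(f1, f2, f3)
  expect_true(all(r >= lo - 1e-9))
  expect_true(all(r <= hi + 1e-9))
})

test_that("fractional order varies continuously across integer boundaries", {
  fs <- 500
  cfg <- aslt_config(5, 100, n_freqs = 10, o_min = 1, o_max = 5, c1 = 3,
                     fs = fs)
  set.seed(4)
  t <- (0:1199) / fs
  x <- cos(2 * pi * 35 * t) + 0.3 * rnorm(1200)
  for (o in c(2, 3)) {
    below <- superlet_response(x, 35, o, cfg)
    above <- superlet_response(x, 35, o + 1e-8, cfg)
    expect_lt(max(abs(below - above)) / max(below), 1e-6)
  }
})

test_that("spectrogram of a chirp has a monotonically rising ridge", {
  fs <- 500
  t <- (0:2999) / fs
  f0 <- 10; f1 <- 80
  x <- sin(2 * pi * (f0 * t + (f1 - f0) / (2 * max(t)) * t^2))
  cfg <- aslt_config(5, 120, n_freqs = 40, o_min = 1, o_max = 6, fs = fs)
  sp <- aslt_transform(x, cfg)
  expect_true(all(sp$values >= 0))
  interior <- 400:2600
  ridge <- sp$freqs[apply(sp$values[, interior], 2, which.max)]
  # smooth the per-column argmax and demand monotone increase
  sm <- stats::filter(ridge, rep(1 / 101, 101), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) > -1e-9))
  expect_gt(sm[length(sm)], 2 * sm[1])
})

test_that("two simultaneous tones yield two persistent ridges at grid frequencies", {
  fs <- 500
  t <- (0:2999) / fs
  x <- cos(2 * pi * 10 * t) + cos(2 * pi * 80 * t)
  cfg <- aslt_config(5, 120, n_freqs = 40, o_min = 1, o_max = 6, fs = fs)
  sp <- aslt_transform(x, cfg)
  profile <- rowMeans(sp$values[, 500:2500])
  peaks <- local_maxima(profile)
  peaks <- peaks[order(-profile[peaks])][1:2]
  got <- sort(sp$freqs[peaks])
  want <- vapply(c(10, 80), function(f) {
    sp$freqs[which.min(abs(sp$freqs - f))]
  }, numeric(1))
  expect_equal(got, want, tolerance = 0.05)
})

test_that("transform is time-shift equivariant away from edges", {
  fs <- 500
  t <- (0:2399) / fs
  set.seed(6)
  x <- sin(2 * pi * 20 * t) * exp(-((t - 2)^2)) + 0.1 * rnorm(2400)
  cfg <- aslt_config(8, 100, n_freqs = 16, o_min = 1, o_max = 4, fs = fs)
  shift <- 200
  xs <- c(numeric(shift), x[1:(length(x) - shift)])
  a <- aslt_transform(x, cfg)$values
  b <- aslt_transform(xs, cfg)$values
  interior <- 700:1700
  expect_equal(b[, interior + shift], a[, interior], tolerance = 0.02)
})

test_that("zero signals produce zero spectrograms and invalid configs error", {
  cfg <- aslt_config(5, 100, n_freqs = 8, o_min = 1, o_max = 3, fs = 500)
  sp <- aslt_transform(numeric(1500), cfg)
  expect_equal(max(sp$values), 0)
  expect_error(aslt_config(f_min = 10, f_max = 5), "f_min")
  expect_error(aslt_config(f_min = 1, f_max = 400, fs = 500), "Nyquist")
  expect_error(morlet_response(1:10, 300, 3, 500), "fs/2")
  expect_error(aslt_transform(numeric(100), cfg), "shorter")
})

test_that("render_image obeys range, shape, and degenerate-input contracts", {
  cfg <- aslt_config(5, 100, n_freqs = 20, o_min = 1, o_max = 3, fs = 500)
  t <- (0:1499) / 500
  sp <- aslt_transform(sin(2 * pi * 30 * t), cfg)
  img <- render_image(sp, size = 224)
  expect_equal(dim(img), c(224L, 224L))
  expect_equal(min(img), 0)
  expect_equal(max(img), 1)

  # arbitrary rectangular input resizes to the requested square
  sp$values <- matrix(runif(100 * 300), 100, 300)
  expect_equal(dim(render_image(sp, size = 64)), c(64L, 64L))

  sp$values <- matrix(0, 20, 1500)
  img0 <- render_image(sp, size = 32)
  expect_equal(max(abs(img0)), 0)
})
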