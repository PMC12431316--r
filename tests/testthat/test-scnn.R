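test_that("if_step follows the leak-free accumulate-fire-reset recurrence", {
  s <- if_step(0.4, 0.3)
  expect_equal(s$V, 0.7)
  expect_equal(s$spike, 0)
  s <- if_step(0.8, 0.5)
  expect_equal(s$V, 0)
  expect_equal(s$spike, 1)
  # subtract mode keeps the residual
  s <- if_step(0.8, 0.5, if_config(reset_mode = "subtract"))
  expect_equal(s$V, 0.3)
})

test_that("if_step matches a brute-force simulation for random drives", {
  brute <- function(X, theta, mode) {
    V <- 0; S <- numeric(length(X)); Vs <- numeric(length(X))
    for (t in seq_along(X)) {
      V <- V + X[t]
      if (V >= theta) {
        S[t] <- 1
        V <- if (mode == "hard") 0 else V - theta
      }
      Vs[t] <- V
    }
    list(S = S, Vs = Vs)
  }
  set.seed(8)
  for (mode in c("hard", "subtract")) {
    for (rep in 1:5) {
      X <- rnorm(40, 0.2, 0.5)
      cfg <- if_config(reset_mode = mode)
      V <- 0; S <- numeric(40); Vs <- numeric(40)
      for (t in 1:40) {
        st <- if_step(V, X[t], cfg)
        V <- st$V; S[t] <- st$spike; Vs[t] <- st$V
      }
      ref <- brute(X, 1, mode)
      expect_equal(S, ref$S)
      expect_equal(Vs, ref$Vs)
    }
  }
})

test_that("constant subthreshold drive fires with period ceil(threshold / X)", {
  for (X in c(0.25, 0.3, 0.5, 0.11)) {
    V <- 0; fires <- integer(0)
    for (t in 1:40) {
      st <- if_step(V, X)
      V <- st$V
      if (st$spike == 1) fires <- c(fires, t)
    }
    period <- ceiling(1 / X)
    expect_equal(fires, seq(period, 40, by = period))
  }
})

test_that("the ATan surrogate has the contracted value, symmetry and slope", {
  expect_equal(surrogate_sigma(0), 0.5)
  set.seed(9)
  x <- rnorm(50, sd = 3)
  expect_equal(surrogate_sigma(x) + surrogate_sigma(-x), rep(1, 50))
  # monotone, bounded in (0, 1)
  xs <- sort(x)
  expect_true(all(diff(surrogate_sigma(xs)) > 0))
  expect_true(all(surrogate_sigma(xs) > 0 & surrogate_sigma(xs) < 1))
  # derivative at 0 is alpha / 2 (numerically)
  for (alpha in c(0.5, 2, 5)) {
    num <- (surrogate_sigma(1e-7, alpha) - surrogate_sigma(-1e-7, alpha)) / 2e-7
    expect_equal(num, alpha / 2, tolerance = 1e-6)
    expect_equal(spikecardio:::surrogate_grad(0, alpha), alpha / 2)
  }
  # large alpha approaches the Heaviside step away from 0
  expect_gt(surrogate_sigma(0.1, 1e4), 0.99)
  expect_lt(surrogate_sigma(-0.1, 1e4), 0.01)
})

test_that("architecture shape arithmetic matches the layer walk", {
  sh <- network_shapes(scnn_config(in_size = 224))
  expect_equal(sh$h_out[sh$layer == "conv4"], 14L) # 7 x 7 after pooling
  expect_equal(sh$c_out[sh$layer == "conv4"], 256L)
  expect_equal(sh$c_in[sh$layer == "fc1"], 256L * 7L * 7L)
  expect_equal(sh$c_in[sh$layer == "fc1"], 12544L)
  expect_equal(sh$c_out[sh$layer == "fc1"], 512L)
  expect_equal(sh$c_out[sh$layer == "fc2"], 2L)

  sh3 <- network_shapes(scnn_config(in_size = 224, n_conv_blocks = 3))
  expect_equal(sh3$h_out[sh3$layer == "conv3"], 28L) # 14 x 14 after pooling
  expect_equal(sh3$c_in[sh3$layer == "fc1"], 128L * 14L * 14L)

  expect_error(scnn_config(in_size = 100), "divisible")
})

test_that("layer primitives backpropagate exact gradients", {
  cf <- spikecardio:::conv_forward; cb <- spikecardio:::conv_backward
  numgrad <- function(f, p, eps = 1e-6) {
    g <- p * 0
    for (i in seq_along(p)) {
      p1 <- p; p1[i] <- p[i] + eps
      p2 <- p; p2[i] <- p[i] - eps
      g[i] <- (f(p1) - f(p2)) / (2 * eps)
    }
    g
  }
  set.seed(11)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  W <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  b <- rnorm(3) * 0.1
  fw <- cf(x, W, b, stride = 1, pad = 1)
  bw <- cb(cos(fw$y), W, fw$cache)
  expect_equal(bw$dW, numgrad(function(w) sum(sin(cf(x, w, b, 1, 1)$y)), W),
               tolerance = 1e-6)
  expect_equal(bw$dx, numgrad(function(x0) sum(sin(cf(x0, W, b, 1, 1)$y)), x),
               tolerance = 1e-6)

  # stride-2 7x7 with pad 3 (the stem convolution geometry)
  x2 <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  W2 <- array(rnorm(7 * 7 * 1 * 2) * 0.2, c(7, 7, 1, 2))
  fw2 <- cf(x2, W2, numeric(2), stride = 2, pad = 3)
  bw2 <- cb(cos(fw2$y), W2, fw2$cache)
  expect_equal(bw2$dx,
               numgrad(function(x0) sum(sin(cf(x0, W2, numeric(2), 2, 3)$y)), x2),
               tolerance = 1e-6)

  bf <- spikecardio:::bn_forward; bb <- spikecardio:::bn_backward
  g <- rnorm(2); be <- rnorm(2)
  fb <- bf(x, g, be, numeric(2), rep(1, 2), training = TRUE)
  bwb <- bb(cos(fb$y), g, fb$cache)
  expect_equal(bwb$dx,
               numgrad(function(x0) sum(sin(bf(x0, g, be, numeric(2),
                                               rep(1, 2), TRUE)$y)), x),
               tolerance = 1e-5)

  pf <- spikecardio:::maxpool_forward; pb <- spikecardio:::maxpool_backward
  fp <- pf(x)
  expect_equal(pb(cos(fp$y), fp$cache),
               numgrad(function(x0) sum(sin(pf(x0)$y)), x),
               tolerance = 1e-6)
})

test_that("forward pass honours spiking semantics and determinism", {
  cfg <- scnn_config(in_size = 64, T_steps = 2)
  net <- build_network(cfg, seed = 3)

  # zero input, zero biases: no spikes anywhere, equal class probabilities
  f0 <- scnn_forward(net, array(0, c(64, 64, 1)), collect_trace = TRUE)
  expect_equal(f0$probs[, 1], c(0.5, 0.5))
  expect_equal(sum(vapply(f0$trace, `[[`, numeric(1), "total_spikes")), 0)

  set.seed(12)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  f1 <- scnn_forward(net, img, collect_trace = TRUE)
  f2 <- scnn_forward(net, img)
  expect_identical(f1$probs, f2$probs) # deterministic, state-isolated
  expect_true(all(colSums(f1$probs) - 1 < 1e-9))
  expect_true(all(f1$firing_counts >= 0 & f1$firing_counts <= cfg$T_steps))
  # single-step firing counts are binary
  fT1 <- scnn_forward(net, img, T_steps = 1)
  expect_true(all(fT1$firing_counts %in% c(0, 1)))

  # state isolation: same image alone or in a batch gives the same output
  f_solo <- scnn_forward(net, img[, , 2, drop = FALSE])
  expect_equal(f_solo$probs[, 1], f1$probs[, 2])

  expect_error(scnn_forward(net, array(0, c(32, 32, 1))), "expects")
})

test_that("cosine annealing starts at lr0 and ends near zero", {
  expect_equal(cosine_lr(0, 150, 0.01), 0.01)
  expect_lt(cosine_lr(149, 150, 0.01), 1e-4)
  lrs <- vapply(0:149, cosine_lr, numeric(1), epochs = 150, lr0 = 0.01)
  expect_true(all(diff(lrs) < 0))
})

test_that("training reduces the loss on a small separable image task", {
  set.seed(13)
  N <- 32
  imgs <- array(0, c(64, 64, N))
  labs <- rep(c(-1L, 1L), N / 2)
  for (i in 1:N) {
    base <- matrix(runif(64 * 64, 0, 0.3), 64, 64)
    rows <- if (labs[i] > 0) 1:32 else 33:64
    base[rows, ] <- base[rows, ] + 0.6
    imgs[, , i] <- pmin(base, 1)
  }
  fit <- scnn_train(imgs, labs, scnn_config(in_size = 64, T_steps = 2),
                    train_config(lr = 0.001, epochs = 3, seed = 1))
  h <- fit$history
  expect_lt(h$train_loss[3], h$train_loss[1])
  expect_equal(h$lr[1], 0.001)
  ev <- spikecardio:::scnn_evaluate(fit$net, imgs, labs)
  expect_gt(ev$acc, 0.7)
})
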