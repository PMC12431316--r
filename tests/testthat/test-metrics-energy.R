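test_that("metric formulas agree with a brute-force recount of predictions", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(20:120, 1)
    truth <- sample(c(-1L, 1L), n, replace = TRUE)
    pred <- ifelse(stats::runif(n) < 0.3, -truth, truth)
    cc <- confusion_counts(pred, truth)
    m <- compute_metrics(cc)
    # recount oracle straight from the raw vectors
    expect_equal(m$Acc, 100 * mean(pred == truth))
    if (any(truth > 0)) {
      expect_equal(m$Sen, 100 * mean(pred[truth > 0] > 0))
    }
    if (any(truth < 0)) {
      expect_equal(m$Spe, 100 * mean(pred[truth < 0] < 0))
    }
    tp <- sum(pred > 0 & truth > 0)
    expect_equal(m$F1, 100 * 2 * tp /
                   (2 * tp + sum(pred > 0 & truth < 0) + sum(pred < 0 & truth > 0)))
  }
})

test_that("degenerate denominators are undefined, not zero", {
  m <- compute_metrics(list(TP = 10, TN = 0, FP = 0, FN = 0))
  expect_equal(m$Acc, 100)
  expect_equal(m$Sen, 100)
  expect_equal(m$F1, 100)
  expect_true(is.na(m$Spe))
})

test_that("AUC matches the rank-sum oracle and is monotone-invariant", {
  rank_auc <- function(scores, labels) {
    pos <- scores[labels > 0]; neg <- scores[labels < 0]
    (mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))) * 100
  }
  set.seed(18)
  for (i in 1:10) {
    n <- 60
    labels <- sample(c(-1L, 1L), n, replace = TRUE, prob = c(0.4, 0.6))
    scores <- stats::runif(n) + 0.3 * (labels > 0)
    cc <- confusion_counts(ifelse(scores > 0.5, 1L, -1L), labels)
    m <- compute_metrics(cc, scores, labels)
    expect_equal(m$AUC, rank_auc(scores, labels), tolerance = 1e-9)
    # strictly monotone transform leaves AUC unchanged
    m2 <- compute_metrics(cc, exp(3 * scores), labels)
    expect_equal(m2$AUC, m$AUC, tolerance = 1e-9)
  }
  # uninformative constant scores
  labels <- rep(c(-1L, 1L), 10)
  m3 <- compute_metrics(confusion_counts(labels, labels),
                        rep(0.25, 20), labels)
  expect_equal(m3$AUC, 50)
})

test_that("layer spike rates divide spikes by neurons, overall pools layers", {
  tr <- list(
    list(layer = "a", total_spikes = 25, n_neurons = 10),
    list(layer = "out", total_spikes = 6, n_neurons = 2)
  )
  r <- layer_spike_rates(tr, T_steps = 6)
  expect_equal(r$layers$spike_rate, c(2.5, 3.0))
  expect_equal(r$overall, 31 / 12)

  # recount oracle on a random trace
  set.seed(19)
  trace <- lapply(1:7, function(i) {
    list(layer = paste0("l", i), total_spikes = stats::rpois(1, 40),
         n_neurons = sample(5:50, 1))
  })
  rr <- layer_spike_rates(trace, 4)
  spikes <- vapply(trace, `[[`, numeric(1), "total_spikes")
  neurons <- vapply(trace, `[[`, numeric(1), "n_neurons")
  expect_equal(rr$layers$spike_rate, spikes / neurons)
  expect_equal(rr$overall, sum(spikes) / sum(neurons))

  expect_equal(layer_spike_rates(list(list(layer = "z", total_spikes = 0,
                                           n_neurons = 9)), 2)$overall, 0)
  expect_error(layer_spike_rates(list(), 2), "empty")
  expect_error(layer_spike_rates(list(list(layer = "x", n_neurons = 3)), 2),
               "missing")
})

test_that("energy report identities hold and respond to the spike rate", {
  r <- energy_report(op_ann = 1e8, overall_spike_rate = 0.5)
  expect_equal(r$op_snn, 0.5 * 1e8)
  expect_equal(r$energy_ann_uJ, 1e8 * 4.6 * 1e-6)
  expect_equal(r$energy_snn_uJ, 0.5e8 * 0.9 * 1e-6)
  expect_equal(r$ratio_ann_over_snn, r$energy_ann_uJ / r$energy_snn_uJ)
  # rate 1: the ratio is exactly e_mac / e_add; halving the rate doubles it
  r1 <- energy_report(1e6, 1)
  expect_equal(r1$ratio_ann_over_snn, 4.6 / 0.9)
  expect_equal(energy_report(1e6, 0.5)$ratio_ann_over_snn,
               2 * r1$ratio_ann_over_snn)
  # zero activity is flagged, not divided by
  r0 <- energy_report(1e6, 0)
  expect_true(is.infinite(r0$ratio_ann_over_snn))
  expect_true(r0$zero_rate)
})

test_that("ANN operation counts match an independent layer enumeration", {
  expect_equal(count_ann_ops(scnn_config(in_size = 64, fc_hidden = 512,
                                         n_conv_blocks = 4))$per_layer$macs[6],
               1024)
  # independent walk of the default 224 network, written out longhand
  conv <- function(k, cin, cout, hout) k^2 * cin * cout * hout^2
  expected <- conv(7, 1, 32, 112) + conv(3, 32, 64, 56) +
    conv(3, 64, 128, 28) + conv(3, 128, 256, 14) +
    (256 * 7 * 7) * 512 + 512 * 2
  got <- count_ann_ops(scnn_config(in_size = 224))
  expect_equal(got$total, expected)
  # single conv layer sanity: 3x3, 1->1 channel, 4x4 output = 144 MACs
  expect_equal(conv(3, 1, 1, 4), 144)
})

test_that("comparison table reproduces total-energy arithmetic", {
  tab <- comparison_table(list(
    list(label = "snn", ops_millions = c(145.8, 87.1), e_per_op_pJ = 0.9,
         acc_percent = 89.74),
    list(label = "ann", ops_millions = c(16.5, 16.9), e_per_op_pJ = 4.6,
         acc_percent = 87.30)
  ))
  expect_equal(tab$total_energy_uJ, c(232.9 * 0.9, 33.4 * 4.6))
  expect_error(comparison_table(list(list(label = "x"))), "ops_millions")
})
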