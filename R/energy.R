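# Spike-rate accounting and CMOS energy model.
#
# A spiking network replaces the multiply-accumulate (MAC) of the
# isomorphic conventional network with event-driven accumulates: its
# operation count is the ANN MAC count scaled by the spike rate
# (spikes per neuron over all inference time steps).  Per-operation
# energies default to 45 nm CMOS figures: 0.9 pJ for a 32-bit FP add,
# 3.7 pJ for a multiply, 4.6 pJ for a fused MAC.

E_ADD_PJ <- 0.9
E_MULT_PJ <- 3.7
E_MAC_PJ <- E_ADD_PJ + E_MULT_PJ

#' Per-layer and overall spike rates
#'
#' The spike rate of a layer is its total spike count over all inference
#' time steps divided by its neuron count; the overall rate is the total
#' spike count of all layers over the total neuron count.
#'
#' @param trace list of per-layer records, each with `layer`,
#'   `total_spikes` (over all time steps, per sample), and `n_neurons`.
#' @param T_steps number of inference time steps the trace covers (stored
#'   on the report for reference).
#' @return a `spike_rate_report`: `layers` (data.frame with `layer`,
#'   `total_spikes`, `n_neurons`, `spike_rate`) and `overall` rate.
#' @export
layer_spike_rates <- function(trace, T_steps) {
  if (!length(trace)) stop_invalid("empty spike trace")
  for (l in trace) {
    if (is.null(l$total_spikes) || is.null(l$n_neurons)) {
      stop_invalid("trace entry missing total_spikes or n_neurons")
    }
  }
  layers <- data.frame(
    layer = vapply(trace, function(l) as.character(l$layer), ""),
    total_spikes = vapply(trace, function(l) as.numeric(l$total_spikes), 0),
    n_neurons = vapply(trace, function(l) as.numeric(l$n_neurons), 0)
  )
  layers$spike_rate <- layers$total_spikes / layers$n_neurons
  structure(list(layers = layers,
                 overall = sum(layers$total_spikes) / sum(layers$n_neurons),
                 T_steps = T_steps),
            class = "spike_rate_report")
}

#' MAC count of the isomorphic conventional network
#'
#' Sums `k^2 * C_in * C_out * H_out * W_out` over convolution layers and
#' `in * out` over fully connected layers, one MAC per product
#' (the dominant-term convention: pooling and batchnorm are excluded).
#'
#' @param net_cfg an [scnn_config()].
#' @return list with `total` MACs and `per_layer` breakdown.
#' @export
count_ann_ops <- function(net_cfg) {
  shapes <- network_shapes(net_cfg)
  ops <- ifelse(shapes$type == "conv",
                shapes$k^2 * shapes$c_in * shapes$c_out *
                  shapes$h_out * shapes$w_out,
                shapes$c_in * shapes$c_out)
  list(total = sum(ops),
       per_layer = data.frame(layer = shapes$layer, macs = ops))
}

#' Energy report of an SNN against its isomorphic ANN
#'
#' `OP_SNN = spike_rate * OP_ANN`; the SNN pays `e_add` per accumulate and
#' the ANN `e_mac` per MAC, so the ANN/SNN energy ratio is
#' `e_mac / (spike_rate * e_add)` — `e_mac / e_add` (about 5.1 with the
#' default energies) at a spike rate of 1, and larger as activity gets
#' sparser.
#'
#' @param op_ann MAC count of the isomorphic ANN (> 0).
#' @param overall_spike_rate spikes per neuron over all inference steps.
#' @param e_mac,e_add per-operation energies in pJ (defaults 4.6 and 0.9,
#'   45 nm CMOS).
#' @return an `energy_report`: `op_ann`, `op_snn`, `energy_ann_uJ`,
#'   `energy_snn_uJ`, `ratio_ann_over_snn` (`Inf` with `zero_rate = TRUE`
#'   when the spike rate is 0).
#' @export
energy_report <- function(op_ann, overall_spike_rate,
                          e_mac = E_MAC_PJ, e_add = E_ADD_PJ) {
  if (op_ann <= 0) stop_invalid("op_ann must be > 0")
  if (overall_spike_rate < 0) stop_invalid("spike rate must be >= 0")
  op_snn <- overall_spike_rate * op_ann
  zero_rate <- overall_spike_rate == 0
  structure(list(
    op_ann = op_ann, op_snn = op_snn,
    overall_spike_rate = overall_spike_rate,
    e_mac_pJ = e_mac, e_add_pJ = e_add,
    energy_ann_uJ = op_ann * e_mac * 1e-6,
    energy_snn_uJ = op_snn * e_add * 1e-6,
    ratio_ann_over_snn = if (zero_rate) Inf else e_mac / (overall_spike_rate * e_add),
    zero_rate = zero_rate
  ), class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf(
    "ANN: %.1fM MAC = %.1f uJ | SNN: rate %.2f -> %.1fM ACC = %.1f uJ | ANN/SNN %.1fx\n",
    x$op_ann / 1e6, x$energy_ann_uJ, x$overall_spike_rate,
    x$op_snn / 1e6, x$energy_snn_uJ, x$ratio_ann_over_snn))
  invisible(x)
}

#' Energy/accuracy comparison table
#'
#' Total-energy arithmetic for a set of models: each entry carries its
#' per-branch operation counts (in millions), its per-operation energy in
#' pJ (`e_add`-style for spiking models, `e_mac`-style for conventional
#' ones), and optionally an accuracy.  Total energy in uJ is
#' `sum(ops) * e_per_op` (1e6 ops x pJ = 1e-6 uJ x 1e6 = uJ).
#'
#' @param entries list of entries: each a list with `label`, `ops_millions`
#'   (numeric vector, one element per model branch), `e_per_op_pJ`, and
#'   optionally `acc_percent`.
#' @return data.frame with `label`, `total_ops_millions`,
#'   `total_energy_uJ`, `acc_percent`.
#' @export
comparison_table <- function(entries) {
  rows <- lapply(entries, function(e) {
    if (is.null(e$label) || is.null(e$ops_millions) || is.null(e$e_per_op_pJ)) {
      stop_invalid("each entry needs label, ops_millions, e_per_op_pJ")
    }
    data.frame(label = e$label,
               total_ops_millions = sum(e$ops_millions),
               total_energy_uJ = sum(e$ops_millions) * e$e_per_op_pJ,
               acc_percent = e$acc_percent %||% NA_real_)
  })
  do.call(rbind, rows)
}
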