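#' Integrate-and-fire neuron configuration
#'
#' @param threshold firing threshold of the membrane potential (default 1).
#' @param reset_potential potential after a spike in hard-reset mode.
#' @param reset_mode `"hard"` (reset to `reset_potential`, default) or
#'   `"subtract"` (subtract the threshold).
#' @return an `if_config` list.
#' @export
if_config <- function(threshold = 1.0, reset_potential = 0.0,
                      reset_mode = c("hard", "subtract")) {
  reset_mode <- match.arg(reset_mode)
  if (threshold <= reset_potential) {
    stop_invalid("threshold must exceed reset_potential")
  }
  structure(list(threshold = threshold, reset_potential = reset_potential,
                 reset_mode = reset_mode), class = "if_config")
}

#' One discrete integrate-and-fire step
#'
#' The leak-free subthreshold dynamics `V[t] - V[t-1] = X[t]`: the candidate
#' potential is `V_prev + X`; a spike is emitted iff it reaches the
#' threshold, upon which the potential hard-resets to `reset_potential`
#' (or has the threshold subtracted in `"subtract"` mode).
#'
#' @param V_prev membrane potential(s) before the step (vectorised).
#' @param X input current(s) at this step.
#' @param cfg an [if_config()].
#' @return list with `V` (post-step potential) and `spike` (0/1).
#' @export
if_step <- function(V_prev, X, cfg = if_config()) {
  Vc <- V_prev + X
  spike <- as.numeric(Vc >= cfg$threshold)
  V <- if (cfg$reset_mode == "hard") {
    Vc * (1 - spike) + cfg$reset_potential * spike
  } else {
    Vc - cfg$threshold * spike
  }
  list(V = V, spike = spike)
}

#' Surrogate spike nonlinearity (ATan)
#'
#' `g(x) = (1/pi) * atan((pi/2) * alpha * x) + 1/2`, the smooth sigmoid used
#' in the backward pass in place of the Heaviside spike function; the
#' forward pass still emits binary spikes.  Its derivative at 0 is
#' `alpha / 2`, and `alpha -> Inf` approaches the step function.
#'
#' @param x membrane drive (vectorised).
#' @param alpha slope scale (> 0, default 2).
#' @return values in (0, 1).
#' @export
surrogate_sigma <- function(x, alpha = 2.0) {
  if (alpha <= 0) stop_invalid("alpha must be > 0")
  atan(pi / 2 * alpha * x) / pi + 0.5
}

# derivative of surrogate_sigma
surrogate_grad <- function(x, alpha = 2.0) {
  (alpha / 2) / (1 + (pi / 2 * alpha * x)^2)
}

#' Spiking convolutional network configuration
#'
#' The architecture: `n_conv_blocks` convolutional spiking blocks, each
#' `conv -> batchnorm -> IF -> 2x2 maxpool`.  Block 1 is a 7x7 convolution
#' with stride 2 taking 1 channel to `base_channels`; later blocks are 3x3,
#' padding 1, doubling the channel count each time.  The flattened features
#' feed a `fc_hidden`-unit spiking layer and a final `n_classes`-unit
#' spiking layer.  The static input image is presented at each of `T` time
#' steps and the output spike vectors are averaged over time (temporal mean
#' pooling) before the softmax.
#'
#' @param in_size input image side in pixels; must be divisible by
#'   `2^(n_conv_blocks + 1)` (one stride-2 convolution plus one 2x pooling
#'   per block).
#' @param base_channels channels after block 1 (default 32).
#' @param n_conv_blocks number of convolutional spiking blocks (default 4;
#'   3 and 5 are supported for depth ablations).
#' @param T_steps number of temporal presentations (default 6).
#' @param fc_hidden hidden width of the first fully connected spiking layer.
#' @param n_classes output classes (default 2).
#' @param neuron an [if_config()].
#' @param alpha surrogate-gradient slope ([surrogate_sigma()]).
#' @return an `scnn_config` list.
#' @export
scnn_config <- function(in_size = 224, base_channels = 32, n_conv_blocks = 4,
                        T_steps = 6, fc_hidden = 512, n_classes = 2,
                        neuron = if_config(), alpha = 2.0) {
  div <- 2^(n_conv_blocks + 1)
  if (in_size %% div != 0) {
    stop_invalid("in_size (%d) must be divisible by 2^(n_conv_blocks+1) = %d",
                 in_size, div)
  }
  if (T_steps < 1) stop_invalid("T_steps must be >= 1")
  structure(list(in_size = as.integer(in_size),
                 base_channels = as.integer(base_channels),
                 n_conv_blocks = as.integer(n_conv_blocks),
                 T_steps = as.integer(T_steps),
                 fc_hidden = as.integer(fc_hidden),
                 n_classes = as.integer(n_classes),
                 neuron = neuron, alpha = alpha),
            class = "scnn_config")
}

#' Layer-by-layer shape walk of the architecture
#'
#' Enumerates every layer with its output shape and, for parameterised
#' layers, the kernel geometry — the basis for parameter allocation and for
#' the ANN operation count.
#'
#' @param cfg an [scnn_config()].
#' @return data.frame with columns `layer`, `type`, `k`, `stride`, `pad`,
#'   `c_in`, `c_out`, `h_out`, `w_out` (fully connected layers use
#'   `c_in`/`c_out` as input/output widths and `h_out = w_out = 1`).
#' @export
network_shapes <- function(cfg) {
  rows <- list()
  h <- cfg$in_size; c_prev <- 1L
  for (b in seq_len(cfg$n_conv_blocks)) {
    if (b == 1) {
      k <- 7L; stride <- 2L; pad <- 3L; c_out <- cfg$base_channels
    } else {
      k <- 3L; stride <- 1L; pad <- 1L; c_out <- c_prev * 2L
    }
    h <- conv_out_dim(h, k, stride, pad)
    rows[[length(rows) + 1]] <- data.frame(
      layer = sprintf("conv%d", b), type = "conv", k = k, stride = stride,
      pad = pad, c_in = c_prev, c_out = c_out, h_out = h, w_out = h)
    h <- h %/% 2L # maxpool
    c_prev <- c_out
  }
  flat <- c_prev * h * h
  rows[[length(rows) + 1]] <- data.frame(
    layer = "fc1", type = "fc", k = NA, stride = NA, pad = NA,
    c_in = flat, c_out = cfg$fc_hidden, h_out = 1L, w_out = 1L)
  rows[[length(rows) + 1]] <- data.frame(
    layer = "fc2", type = "fc", k = NA, stride = NA, pad = NA,
    c_in = cfg$fc_hidden, c_out = cfg$n_classes, h_out = 1L, w_out = 1L)
  do.call(rbind, rows)
}

#' Build (initialise) a spiking convolutional network
#'
#' Allocates He-initialised convolution and fully connected weights, unit
#' batchnorm scales, and reports per-layer shapes.
#'
#' @param cfg an [scnn_config()].
#' @param seed integer seed for the weight draw.
#' @return an `scnn` object (list of layers plus the config).
#' @export
build_network <- function(cfg, seed = 1L) {
  shapes <- network_shapes(cfg)
  with_seed(seed, {
    layers <- list()
    for (i in seq_len(nrow(shapes))) {
      s <- shapes[i, ]
      if (s$type == "conv") {
        fan_in <- s$k^2 * s$c_in
        W <- array(stats::rnorm(s$k^2 * s$c_in * s$c_out, sd = sqrt(2 / fan_in)),
                   c(s$k, s$k, s$c_in, s$c_out))
        layers[[length(layers) + 1]] <- list(
          type = "conv", name = s$layer, W = W, b = numeric(s$c_out),
          stride = s$stride, pad = s$pad)
        layers[[length(layers) + 1]] <- list(
          type = "bn", name = paste0(s$layer, "_bn"),
          gamma = rep(1, s$c_out), beta = numeric(s$c_out),
          running_mean = numeric(s$c_out), running_var = rep(1, s$c_out))
        layers[[length(layers) + 1]] <- list(
          type = "if", name = paste0(s$layer, "_if"),
          n_neurons = s$c_out * s$h_out * s$w_out)
        layers[[length(layers) + 1]] <- list(
          type = "pool", name = paste0(s$layer, "_pool"))
      } else {
        if (!any(vapply(layers, function(l) l$type == "flatten", logical(1)))) {
          layers[[length(layers) + 1]] <- list(type = "flatten", name = "flatten")
        }
        W <- matrix(stats::rnorm(s$c_in * s$c_out, sd = sqrt(2 / s$c_in)),
                    s$c_out, s$c_in)
        layers[[length(layers) + 1]] <- list(
          type = "fc", name = s$layer, W = W, b = numeric(s$c_out))
        layers[[length(layers) + 1]] <- list(
          type = "if", name = paste0(s$layer, "_if"), n_neurons = s$c_out)
      }
    }
    structure(list(cfg = cfg, layers = layers, shapes = shapes),
              class = "scnn")
  })
}

#' @export
print.scnn <- function(x, ...) {
  cat(sprintf("<scnn> %d conv blocks, in %dx%d, T=%d\n",
              x$cfg$n_conv_blocks, x$cfg$in_size, x$cfg$in_size,
              x$cfg$T_steps))
  print(x$shapes[, c("layer", "type", "c_in", "c_out", "h_out", "w_out")])
  invisible(x)
}

# IF dynamics over T steps on a (M x N*T) matrix view (time-major blocks).
# Returns spikes plus the per-step candidate potentials needed for BPTT.
if_forward_T <- function(x, N, T_steps, neuron) {
  d_in <- dim(x)
  M <- prod(d_in) / (N * T_steps)
  dim(x) <- c(M, N * T_steps)
  S <- matrix(0, M, N * T_steps)
  Vc_list <- vector("list", T_steps)
  V <- matrix(0, M, N)
  for (t in seq_len(T_steps)) {
    idx <- ((t - 1) * N + 1):(t * N)
    Vc <- V + x[, idx, drop = FALSE]
    sp <- (Vc >= neuron$threshold) * 1
    V <- if (neuron$reset_mode == "hard") {
      Vc * (1 - sp) + neuron$reset_potential * sp
    } else {
      Vc - neuron$threshold * sp
    }
    S[, idx] <- sp
    Vc_list[[t]] <- Vc
  }
  dim(S) <- d_in
  list(S = S, cache = list(Vc = Vc_list, d_in = d_in, M = M, N = N,
                           T_steps = T_steps))
}

# BPTT through the IF recurrence; reset is detached (the standard surrogate
# recipe): dL/dVc_t = dL/dS_t * g'(Vc_t - theta) + dL/dV_t * (1 - S_t).
if_backward_T <- function(dS, cache, neuron, alpha) {
  M <- cache$M; N <- cache$N; T_steps <- cache$T_steps
  d_in <- cache$d_in
  dim(dS) <- c(M, N * T_steps)
  dX <- matrix(0, M, N * T_steps)
  dV <- matrix(0, M, N)
  for (t in rev(seq_len(T_steps))) {
    idx <- ((t - 1) * N + 1):(t * N)
    Vc <- cache$Vc[[t]]
    sp <- (Vc >= neuron$threshold) * 1
    g <- surrogate_grad(Vc - neuron$threshold, alpha)
    dVc <- dS[, idx, drop = FALSE] * g +
      if (neuron$reset_mode == "hard") dV * (1 - sp) else dV
    dX[, idx] <- dVc
    dV <- dVc
  }
  dim(dX) <- d_in
  dX
}

#' Forward pass of the spiking network
#'
#' The static image batch is presented identically at each of `T` time
#' steps (laid out as one batch of `N*T` presentations so batchnorm
#' statistics are shared across steps); IF layers run their recurrence over
#' the step dimension with all membranes starting from reset.  The output
#' probabilities are the softmax of the temporal mean of the final layer's
#' spike vectors.
#'
#' @param net an `scnn` from [build_network()].
#' @param images array `(H, W, N)` (or `(H, W)` for one image) of grayscale
#'   inputs in `[0, 1]`, `H = W = cfg$in_size`.
#' @param T_steps number of time steps (default the config's `T_steps`).
#' @param training use batch statistics (and keep caches for the backward
#'   pass) instead of running statistics.
#' @param collect_trace record per-layer spike counts for energy accounting.
#' @return list with `probs` (`n_classes x N`), `rates` (mean output spikes
#'   per step), `firing_counts` (`n_classes x N`, total spikes over `T`),
#'   `trace` (per-layer spike statistics when requested), and internal
#'   caches when `training = TRUE`.
#' @export
scnn_forward <- function(net, images, T_steps = NULL, training = FALSE,
                         collect_trace = FALSE) {
  cfg <- net$cfg
  T_steps <- T_steps %||% cfg$T_steps
  if (length(dim(images)) == 2) dim(images) <- c(dim(images), 1)
  d <- dim(images)
  if (d[1] != cfg$in_size || d[2] != cfg$in_size) {
    stop_invalid("image is %dx%d but the network expects %dx%d",
                 d[1], d[2], cfg$in_size, cfg$in_size)
  }
  N <- d[3]
  x <- array(rep(images, T_steps), c(d[1], d[2], 1, N * T_steps))
  caches <- vector("list", length(net$layers))
  trace <- list()
  flat_dim <- NULL
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      r <- conv_forward(x, l$W, l$b, l$stride, l$pad)
      x <- r$y; caches[[i]] <- r$cache
    } else if (l$type == "bn") {
      r <- bn_forward(x, l$gamma, l$beta, l$running_mean, l$running_var,
                      training = training)
      x <- r$y; caches[[i]] <- r$cache
      if (training) {
        net$layers[[i]]$running_mean <- r$running_mean
        net$layers[[i]]$running_var <- r$running_var
      }
    } else if (l$type == "if") {
      r <- if_forward_T(x, N, T_steps, cfg$neuron)
      x <- r$S; caches[[i]] <- r$cache
      if (collect_trace) {
        trace[[length(trace) + 1]] <- list(
          layer = l$name, total_spikes = sum(x) / N, n_neurons = l$n_neurons)
      }
    } else if (l$type == "pool") {
      r <- maxpool_forward(x)
      x <- r$y; caches[[i]] <- r$cache
    } else if (l$type == "flatten") {
      flat_dim <- dim(x)
      dim(x) <- c(prod(flat_dim[1:3]), flat_dim[4])
      caches[[i]] <- list(flat_dim = flat_dim)
    } else if (l$type == "fc") {
      r <- fc_forward(x, l$W, l$b)
      x <- r$y; caches[[i]] <- r$cache
    }
  }
  # x: (n_classes x N*T) spikes; temporal mean pooling
  S_out <- x
  dim(S_out) <- c(cfg$n_classes, N, T_steps)
  rates <- apply(S_out, c(1, 2), mean)
  dim(rates) <- c(cfg$n_classes, N)
  probs <- col_softmax(rates)
  out <- list(probs = probs, rates = rates,
              firing_counts = rates * T_steps, N = N, T_steps = T_steps)
  if (collect_trace) out$trace <- trace
  if (training) {
    out$caches <- caches
    out$net <- net # carries updated batchnorm running statistics
  }
  out
}

# Backward pass: takes dL/dS_out (n_classes x N*T) and returns gradients
# for every parameterised layer.
scnn_backward <- function(net, fwd, dS_out) {
  cfg <- net$cfg
  caches <- fwd$caches
  grads <- vector("list", length(net$layers))
  dx <- dS_out
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    if (l$type == "fc") {
      r <- fc_backward(dx, l$W, caches[[i]])
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dx <- r$dx
    } else if (l$type == "flatten") {
      dim(dx) <- caches[[i]]$flat_dim
    } else if (l$type == "pool") {
      dx <- maxpool_backward(dx, caches[[i]])
    } else if (l$type == "if") {
      dx <- if_backward_T(dx, caches[[i]], cfg$neuron, cfg$alpha)
    } else if (l$type == "bn") {
      r <- bn_backward(dx, l$gamma, caches[[i]])
      grads[[i]] <- list(dgamma = r$dgamma, dbeta = r$dbeta)
      dx <- r$dx
    } else if (l$type == "conv") {
      r <- conv_backward(dx, l$W, caches[[i]])
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dx <- r$dx
    }
  }
  grads
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = 0.5 * lr0 * (1 + cos(pi * e / epochs))` for 0-based epoch `e` —
#' `lr0` at the first epoch, decaying towards 0 at the budget's end.
#'
#' @param epoch 0-based epoch index.
#' @param epochs total epoch budget.
#' @param lr0 initial learning rate.
#' @return learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, epochs, lr0 = 0.01) {
  0.5 * lr0 * (1 + cos(pi * epoch / epochs))
}

#' Training configuration
#'
#' @param lr initial Adam learning rate (default 0.01).
#' @param epochs epoch budget (the study uses 150 for ECG, 160 for EPCG).
#' @param batch_size minibatch size (default 16).
#' @param n_folds cross-validation folds (default 5).
#' @param seed integer seed for shuffling and initialisation.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.01, epochs = 150, batch_size = 16,
                         n_folds = 5, seed = 1L) {
  if (lr <= 0) stop_invalid("lr must be > 0")
  if (epochs < 1) stop_invalid("epochs must be >= 1")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "train_config")
}

# Adam state/update over the network's parameter slots.
adam_init <- function(net) {
  lapply(net$layers, function(l) {
    if (l$type %in% c("conv", "fc")) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    } else if (l$type == "bn") {
      list(mg = l$gamma * 0, vg = l$gamma * 0,
           mb = l$beta * 0, vb = l$beta * 0)
    } else NULL
  })
}

adam_step <- function(p, m, v, g, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

apply_grads <- function(net, opt, grads, lr, t) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]; g <- grads[[i]]
    if (is.null(g)) next
    if (l$type %in% c("conv", "fc")) {
      u <- adam_step(l$W, opt[[i]]$mW, opt[[i]]$vW, g$dW, lr, t)
      net$layers[[i]]$W <- u$p; opt[[i]]$mW <- u$m; opt[[i]]$vW <- u$v
      u <- adam_step(l$b, opt[[i]]$mb, opt[[i]]$vb, g$db, lr, t)
      net$layers[[i]]$b <- u$p; opt[[i]]$mb <- u$m; opt[[i]]$vb <- u$v
    } else if (l$type == "bn") {
      u <- adam_step(l$gamma, opt[[i]]$mg, opt[[i]]$vg, g$dgamma, lr, t)
      net$layers[[i]]$gamma <- u$p; opt[[i]]$mg <- u$m; opt[[i]]$vg <- u$v
      u <- adam_step(l$beta, opt[[i]]$mb, opt[[i]]$vb, g$dbeta, lr, t)
      net$layers[[i]]$beta <- u$p; opt[[i]]$mb <- u$m; opt[[i]]$vb <- u$v
    }
  }
  list(net = net, opt = opt)
}

# labels in {-1, +1} -> class index {1, 2}: abnormal (+1) is class 2.
label_to_class <- function(labels) ifelse(labels > 0, 2L, 1L)

#' Train a spiking network with surrogate-gradient backpropagation
#'
#' Cross-entropy on the softmax of the temporally mean-pooled output spikes,
#' backpropagated through time with the ATan surrogate in place of the spike
#' derivative; Adam with a cosine-annealed learning rate.  Neuron membranes
#' restart from reset on every batch.
#'
#' @param images array `(H, W, N)` of training images.
#' @param labels length-`N` labels in {-1, +1}.
#' @param net_cfg an [scnn_config()].
#' @param tr_cfg a [train_config()].
#' @param val_images,val_labels optional held-out set evaluated per epoch.
#' @param verbose print one line per epoch.
#' @return list with `net` (trained), `history` (data.frame: epoch, lr,
#'   train_loss, val_loss, val_acc).
#' @export
scnn_train <- function(images, labels, net_cfg, tr_cfg,
                       val_images = NULL, val_labels = NULL,
                       verbose = FALSE) {
  N <- dim(images)[3]
  if (N < 1) stop_invalid("no training images")
  y_cls <- label_to_class(labels)
  net <- build_network(net_cfg, seed = tr_cfg$seed)
  opt <- adam_init(net)
  history <- list()
  step <- 0
  with_seed(tr_cfg$seed + 1L, {
    for (epoch in seq_len(tr_cfg$epochs) - 1L) {
      lr <- cosine_lr(epoch, tr_cfg$epochs, tr_cfg$lr)
      perm <- sample(N)
      losses <- numeric(0)
      for (start in seq(1, N, by = tr_cfg$batch_size)) {
        idx <- perm[start:min(start + tr_cfg$batch_size - 1, N)]
        nb <- length(idx)
        xb <- images[, , idx, drop = FALSE]
        fwd <- scnn_forward(net, xb, training = TRUE)
        net <- fwd$net
        Y <- matrix(0, net_cfg$n_classes, nb)
        Y[cbind(y_cls[idx], seq_len(nb))] <- 1
        p <- fwd$probs
        losses <- c(losses, -mean(log(pmax(p[cbind(y_cls[idx], seq_len(nb))],
                                           1e-12))))
        drates <- (p - Y) / nb
        dS_out <- matrix(rep(drates / fwd$T_steps, fwd$T_steps),
                         net_cfg$n_classes, nb * fwd$T_steps)
        grads <- scnn_backward(net, fwd, dS_out)
        step <- step + 1
        upd <- apply_grads(net, opt, grads, lr, step)
        net <- upd$net; opt <- upd$opt
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(val_images) && dim(val_images)[3] > 0) {
        ev <- scnn_evaluate(net, val_images, val_labels)
        val_loss <- ev$loss; val_acc <- ev$acc
      }
      history[[epoch + 1]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = mean(losses),
        val_loss = val_loss, val_acc = val_acc)
      if (verbose) {
        message(sprintf("epoch %3d lr %.5f loss %.4f val_loss %s val_acc %s",
                        epoch, lr, mean(losses),
                        format(val_loss, digits = 4),
                        format(val_acc, digits = 4)))
      }
    }
  })
  list(net = net, history = do.call(rbind, history))
}

#' Inference over a batch of images
#'
#' Deterministic, state-isolated inference (running batchnorm statistics,
#' membranes reset per batch).
#'
#' @param net a trained `scnn`.
#' @param images array `(H, W, N)`.
#' @param batch_size evaluation minibatch size.
#' @param collect_trace also accumulate per-layer spike statistics.
#' @return a `prediction_set`: list with `probs` (`n_classes x N`),
#'   `firing_counts`, `pred_class` (1-based), `pred_label` ({-1, +1}), and
#'   `trace` (summed per-layer spike stats per sample) when requested.
#' @export
scnn_predict <- function(net, images, batch_size = 32, collect_trace = FALSE) {
  if (length(dim(images)) == 2) dim(images) <- c(dim(images), 1)
  N <- dim(images)[3]
  probs <- matrix(0, net$cfg$n_classes, N)
  counts <- matrix(0, net$cfg$n_classes, N)
  trace_tot <- NULL
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    fwd <- scnn_forward(net, images[, , idx, drop = FALSE],
                        training = FALSE, collect_trace = collect_trace)
    probs[, idx] <- fwd$probs
    counts[, idx] <- fwd$firing_counts
    if (collect_trace) {
      if (is.null(trace_tot)) {
        trace_tot <- fwd$trace
        for (j in seq_along(trace_tot)) {
          trace_tot[[j]]$total_spikes <- trace_tot[[j]]$total_spikes * length(idx)
        }
      } else {
        for (j in seq_along(trace_tot)) {
          trace_tot[[j]]$total_spikes <- trace_tot[[j]]$total_spikes +
            fwd$trace[[j]]$total_spikes * length(idx)
        }
      }
    }
  }
  out <- list(probs = probs, firing_counts = counts,
              pred_class = apply(probs, 2, which.max))
  out$pred_label <- ifelse(out$pred_class == 2, 1L, -1L)
  if (collect_trace) {
    # per-sample average spike counts per layer
    for (j in seq_along(trace_tot)) {
      trace_tot[[j]]$total_spikes <- trace_tot[[j]]$total_spikes / N
    }
    out$trace <- trace_tot
  }
  structure(out, class = "prediction_set")
}

# Cross-entropy loss and accuracy on a labelled set.
scnn_evaluate <- function(net, images, labels, batch_size = 32) {
  pred <- scnn_predict(net, images, batch_size)
  y_cls <- label_to_class(labels)
  n <- length(labels)
  loss <- -mean(log(pmax(pred$probs[cbind(y_cls, seq_len(n))], 1e-12)))
  acc <- mean(pred$pred_class == y_cls)
  list(loss = loss, acc = acc, pred = pred)
}

#' Cross-validated training
#'
#' Trains one model per requested fold, holding that fold out for
#' validation, and returns per-fold histories plus the fold models.
#'
#' @param images array `(H, W, N)`.
#' @param labels length-`N` labels in {-1, +1}.
#' @param fold_ids length-`N` integer fold assignment (0-based).
#' @param net_cfg,tr_cfg network and training configurations.
#' @param folds_to_run which folds to hold out (default all).
#' @param verbose per-epoch logging.
#' @return list of per-fold results (`fold`, `net`, `history`).
#' @export
scnn_train_cv <- function(images, labels, fold_ids, net_cfg, tr_cfg,
                          folds_to_run = sort(unique(fold_ids)),
                          verbose = FALSE) {
  lapply(folds_to_run, function(f) {
    tr <- which(fold_ids != f)
    va <- which(fold_ids == f)
    if (!length(tr) || !length(va)) stop_invalid("fold %d is empty", f)
    fit <- scnn_train(images[, , tr, drop = FALSE], labels[tr],
                      net_cfg, tr_cfg,
                      val_images = images[, , va, drop = FALSE],
                      val_labels = labels[va], verbose = verbose)
    list(fold = f, net = fit$net, history = fit$history)
  })
}
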