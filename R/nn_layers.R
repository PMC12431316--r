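# Dense-array neural-network primitives used by the spiking network.
#
# Activations are 4-D arrays dim (H, W, C, B) where B is the flattened
# batch*time dimension (time-major blocks: column (t-1)*N + n).  Convolution
# is im2col + GEMM on the BLAS; all backward passes are exact gradients of
# the forward computation.

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  out
}

conv_out_dim <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1

# Patch matrix of a padded input: rows ordered (ki, kj, C) to match the
# column-major flattening of a weight array dim (k, k, C_in, C_out).
im2col <- function(xp, k, stride, h_out, w_out) {
  d <- dim(xp); C <- d[3]; B <- d[4]
  ri <- seq(1, by = stride, length.out = h_out)
  rj <- seq(1, by = stride, length.out = w_out)
  A <- array(0, c(k, k, C, h_out, w_out, B))
  for (dj in 1:k) for (di in 1:k) {
    sl <- xp[ri + di - 1, rj + dj - 1, , , drop = FALSE]
    A[di, dj, , , , ] <- aperm(sl, c(3, 1, 2, 4))
  }
  dim(A) <- c(k * k * C, h_out * w_out * B)
  A
}

conv_forward <- function(x, W, b, stride, pad) {
  d <- dim(x)
  k <- dim(W)[1]; c_in <- dim(W)[3]; c_out <- dim(W)[4]
  stopifnot(d[3] == c_in)
  h_out <- conv_out_dim(d[1], k, stride, pad)
  w_out <- conv_out_dim(d[2], k, stride, pad)
  xp <- pad_hw(x, pad)
  A <- im2col(xp, k, stride, h_out, w_out)
  Wm <- W; dim(Wm) <- c(k * k * c_in, c_out)
  Y <- crossprod(Wm, A) + b # (c_out x h_out*w_out*B), b recycled per column
  dim(Y) <- c(c_out, h_out, w_out, d[4])
  list(y = aperm(Y, c(2, 3, 1, 4)),
       cache = list(A = A, x_dim = d, k = k, stride = stride, pad = pad,
                    h_out = h_out, w_out = w_out))
}

conv_backward <- function(dy, W, cache) {
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  d <- cache$x_dim; c_in <- d[3]; B <- d[4]
  c_out <- dim(W)[4]
  h_out <- cache$h_out; w_out <- cache$w_out
  dY <- aperm(dy, c(3, 1, 2, 4))
  dim(dY) <- c(c_out, h_out * w_out * B)
  dWm <- tcrossprod(cache$A, dY) # (k*k*c_in x c_out)
  dW <- dWm; dim(dW) <- c(k, k, c_in, c_out)
  db <- rowSums(dY)
  Wm <- W; dim(Wm) <- c(k * k * c_in, c_out)
  dA <- Wm %*% dY
  dim(dA) <- c(k, k, c_in, h_out, w_out, B)
  dxp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, c_in, B))
  ri <- seq(1, by = stride, length.out = h_out)
  rj <- seq(1, by = stride, length.out = w_out)
  for (dj in 1:k) for (di in 1:k) {
    sl <- dA[di, dj, , , , , drop = FALSE]
    dim(sl) <- c(c_in, h_out, w_out, B)
    dxp[ri + di - 1, rj + dj - 1, , ] <-
      dxp[ri + di - 1, rj + dj - 1, , , drop = FALSE] + aperm(sl, c(2, 3, 1, 4))
  }
  dx <- if (pad > 0) {
    dxp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), , , drop = FALSE]
  } else dxp
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# Batch normalisation over (H, W, B) per channel.  With the batch laid out
# as N*T columns this shares statistics across the T time steps.
bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  xr <- aperm(x, c(1, 2, 4, 3))
  dim(xr) <- c(d[1] * d[2] * d[4], C)
  if (training) {
    mu <- colMeans(xr)
    va <- colMeans(xr^2) - mu^2
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    running_var <- (1 - momentum) * running_var + momentum * va
  } else {
    mu <- running_mean
    va <- running_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xr, 2, mu, "-"), 2, inv_sd, "*")
  yr <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(yr) <- c(d[1], d[2], d[4], C)
  list(y = aperm(yr, c(1, 2, 4, 3)),
       cache = list(xhat = xhat, inv_sd = inv_sd, d = d, training = training),
       running_mean = running_mean, running_var = running_var)
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$d; C <- d[3]
  dyr <- aperm(dy, c(1, 2, 4, 3))
  dim(dyr) <- c(d[1] * d[2] * d[4], C)
  xhat <- cache$xhat
  dgamma <- colSums(dyr * xhat)
  dbeta <- colSums(dyr)
  m <- nrow(dyr)
  if (cache$training) {
    # gradient through the batch statistics
    t1 <- sweep(dyr, 2, dbeta / m, "-")
    t2 <- sweep(xhat, 2, dgamma / m, "*")
    dxr <- sweep((t1 - t2), 2, gamma * cache$inv_sd, "*")
  } else {
    dxr <- sweep(dyr, 2, gamma * cache$inv_sd, "*")
  }
  dim(dxr) <- c(d[1], d[2], d[4], C)
  list(dx = aperm(dxr, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  s <- list(
    x[io, jo, , , drop = FALSE], x[io + 1, jo, , , drop = FALSE],
    x[io, jo + 1, , , drop = FALSE], x[io + 1, jo + 1, , , drop = FALSE]
  )
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  dim(y) <- c(d[1] / 2, d[2] / 2, d[3], d[4])
  taken <- array(FALSE, dim(y))
  masks <- vector("list", 4)
  for (q in 1:4) {
    m <- (s[[q]] == y) & !taken
    dim(m) <- dim(y)
    masks[[q]] <- m
    taken <- taken | m
  }
  list(y = y, cache = list(masks = masks, d = d))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$d
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  dx <- array(0, d)
  g <- function(q) dy * cache$masks[[q]]
  dx[io, jo, , ] <- g(1)
  dx[io + 1, jo, , ] <- g(2)
  dx[io, jo + 1, , ] <- g(3)
  dx[io + 1, jo + 1, , ] <- g(4)
  dx
}

fc_forward <- function(x, W, b) {
  # x: (in x B)
  list(y = W %*% x + b, cache = list(x = x))
}

fc_backward <- function(dy, W, cache) {
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, cache$x), db = rowSums(dy))
}
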