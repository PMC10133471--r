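# Independent brute-force oracles: nested-loop implementations of the
# convolutional and attention operations, written directly from their
# definitions and kept free of the package's im2col/GEMM code paths.

# direct group depth-wise convolution: per EEG channel c and output map i,
# out[c, i, l] = b[i, c] + sum_j sum_k W[k, j, i, c] * xpad[c, j, pos(l) + k - 1]
oracle_group_conv <- function(x, W, b, stride) {
  C <- dim(x)[1]; Min <- dim(x)[2]; L <- dim(x)[3]; B <- dim(x)[4]
  k <- dim(W)[1]; Mout <- dim(W)[3]
  Lout <- ceiling(L / stride)
  pad <- max((Lout - 1) * stride + k - L, 0)
  pl <- pad %/% 2
  out <- array(0, c(C, Mout, Lout, B))
  for (bb in seq_len(B)) for (cc in seq_len(C)) {
    xp <- matrix(0, Min, L + pad)
    xp[, pl + seq_len(L)] <- x[cc, , , bb]
    for (i in seq_len(Mout)) for (l in seq_len(Lout)) {
      acc <- b[i, cc]
      start <- (l - 1) * stride
      for (j in seq_len(Min)) for (kk in seq_len(k))
        acc <- acc + W[kk, j, i, cc] * xp[j, start + kk]
      out[cc, i, l, bb] <- acc
    }
  }
  out
}

# direct temporal convolution: shared 1 x k kernel per output map swept
# over every channel row, stride 1, SAME padding
oracle_temporal_conv <- function(x, W) {
  C <- dim(x)[1]; L <- dim(x)[2]; B <- dim(x)[3]
  k <- nrow(W); K <- ncol(W)
  pad <- k - 1; pl <- pad %/% 2
  out <- array(0, c(C, K, L, B))
  for (bb in seq_len(B)) for (cc in seq_len(C)) {
    xp <- c(rep(0, pl), x[cc, , bb], rep(0, pad - pl))
    for (i in seq_len(K)) for (l in seq_len(L))
      out[cc, i, l, bb] <- sum(W[, i] * xp[l:(l + k - 1)])
  }
  out
}

# direct depth-wise spatial collapse: out[m, l] = b[m] + sum_c W[c, m] * x[c, m, l]
oracle_spatial_conv <- function(x, W, b) {
  C <- dim(x)[1]; M <- dim(x)[2]; L <- dim(x)[3]; B <- dim(x)[4]
  out <- array(0, c(M, L, B))
  for (bb in seq_len(B)) for (m in seq_len(M)) for (l in seq_len(L))
    out[m, l, bb] <- b[m] + sum(W[, m] * x[, m, l, bb])
  out
}

# direct channel attention: pool along L, per-map affine mix, sigmoid
oracle_channel_attention <- function(f, w_avg, w_max, bias) {
  C <- dim(f)[1]; M <- dim(f)[2]
  g <- matrix(0, C, M)
  for (cc in seq_len(C)) for (m in seq_len(M)) {
    a <- mean(f[cc, m, ]); mx <- max(f[cc, m, ])
    g[cc, m] <- 1 / (1 + exp(-(w_avg[m] * a + w_max[m] * mx + bias[m])))
  }
  g
}

# direct network attention: global pools, shared MLP on each, sum, sigmoid
oracle_network_attention <- function(f, W0, W1) {
  M <- dim(f)[2]
  s_avg <- numeric(M); s_max <- numeric(M)
  for (m in seq_len(M)) {
    s_avg[m] <- mean(f[, m, ])
    s_max[m] <- max(f[, m, ])
  }
  mlp <- function(s) as.numeric(W1 %*% pmax(W0 %*% s, 0))
  1 / (1 + exp(-(mlp(s_avg) + mlp(s_max))))
}

# closed-form parameter count of the assembled network
oracle_param_count <- function(C, K, k, n_blocks, P, n_classes, final_len,
                               H, channel_att = TRUE, network_att = TRUE,
                               variant = "full") {
  n <- k * K               # temporal conv W (no bias)
  n <- n + 2 * K           # batch norm gamma/beta
  for (blk in seq_len(n_blocks)) {
    if (variant == "model1") n <- n + k * K * K + K
    else n <- n + (k * K * K + K) * C        # per-channel kernels + biases
    n <- n + 2 * K                           # block batch norm
    if (variant == "model6") n <- n + H * K + K * H + 7 + 7 + 1
    else {
      if (channel_att) n <- n + 3 * K
      if (network_att) n <- n + H * K + K * H
    }
  }
  n <- n + C * K + K       # spatial conv W + bias
  n <- n + P * K           # point-wise (no bias)
  n <- n + 2 * P           # point-wise batch norm
  n <- n + n_classes * P * final_len
  n
}

# central-difference numerical gradient of the regularised loss
numeric_grad <- function(model, x, Y, lambda, nm, i, eps = 1e-6) {
  params <- model_params(model)
  loss_at <- function(p) {
    fw <- model_forward(model_set_params(model, p), x, training = TRUE)
    cross_entropy_loss(fw$probs, Y,
                       decayed_weights(model_set_params(model, p)), lambda)
  }
  pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
  pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
  (loss_at(pp) - loss_at(pm)) / (2 * eps)
}

# small random feature cube
random_cube <- function(C, M, L, B = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(B)) array(rnorm(C * M * L), c(C, M, L))
  else array(rnorm(C * M * L * B), c(C, M, L, B))
}
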