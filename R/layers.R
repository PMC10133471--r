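# Internal layer machinery.
#
# Tensor layout conventions (R column-major):
#   raw input        : (C, L, B)        channels x samples x batch
#   feature cube     : (C, M, L, B)     channels x maps x length x batch
#   collapsed stage  : (M, L, B)        maps x length x batch
#   flattened stage  : (D, B)
#
# Every layer is a plain list: list(type, params, buffers, meta).
# `layer_forward()` returns list(layer, out, cache); `layer_backward()`
# returns list(dx, grads) with grads named like params. Convolutions are
# realised as compiled im2col gathers + BLAS matrix products (and the
# exact adjoint scatter in the backward pass); correctness is checked
# against nested-loop oracles and numerical gradients in the test suite.

new_layer <- function(type, params = list(), buffers = list(), meta = list()) {
  list(type = type, params = params, buffers = buffers, meta = meta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# SAME-padding amount for kernel k, stride s over length L
.same_pad <- function(L, k, s) {
  Lout <- ceiling(L / s)
  pad <- max((Lout - 1L) * s + k - L, 0L)
  list(Lout = as.integer(Lout), left = as.integer(pad %/% 2L),
       right = as.integer(pad - pad %/% 2L))
}

# ---------------------------------------------------------------- temporal

# params: W (k x K). Input (C, L, B) -> output (C, K, L, B), stride 1,
# SAME padding, one shared 1D kernel per output map swept over every
# channel row. Bias-free (batch norm follows immediately).
temporal_conv_forward <- function(layer, x) {
  W <- layer$params$W
  k <- nrow(W); K <- ncol(W)
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  p <- .same_pad(L, k, 1L)
  d4 <- c(C, 1L, L, B)
  Wrep <- array(W, c(k, K, C))                  # shared across channels
  out <- gconv_fwd(x, d4, Wrep, matrix(0, K, C), k, 1L, p$left, L)
  list(layer = layer, out = out,
       cache = list(x = x, Wrep = Wrep, dims = d, pad = p))
}

temporal_conv_backward <- function(layer, dout, cache) {
  W <- layer$params$W
  k <- nrow(W); K <- ncol(W)
  d <- cache$dims; C <- d[1]; L <- d[2]; B <- d[3]
  d4 <- c(C, 1L, L, B)
  res <- gconv_bwd(cache$x, d4, cache$Wrep, dout, k, 1L, cache$pad$left, L)
  dx <- res$dx
  dim(dx) <- d
  dW <- rowSums(res$dW, dims = 2L)              # shared kernel: sum over C
  list(dx = dx, grads = list(W = dW))
}

# ------------------------------------------------------------- group conv

# params: W (k x Min x Mout x C), b (Mout x C). One independent 1D kernel
# per EEG channel per (input map, output map) pair; rows of different
# channels never mix. Input (C, Min, L, B) -> (C, Mout, Lout, B).
group_conv_forward <- function(layer, x) {
  W <- layer$params$W; b <- layer$params$b
  k <- dim(W)[1]; Min <- dim(W)[2]; Mout <- dim(W)[3]
  d <- dim(x); L <- d[3]
  s <- layer$meta$stride
  p <- .same_pad(L, k, s)
  Wm <- aperm(W, c(2, 1, 3, 4))                 # (Min, k, Mout, C)
  dim(Wm) <- c(Min * k, Mout, dim(W)[4])
  out <- gconv_fwd(x, d, Wm, b, k, s, p$left, p$Lout)
  list(layer = layer, out = out,
       cache = list(x = x, Wm = Wm, dims = d, pad = p))
}

group_conv_backward <- function(layer, dout, cache) {
  W <- layer$params$W
  k <- dim(W)[1]; Min <- dim(W)[2]; Mout <- dim(W)[3]
  d <- cache$dims
  s <- layer$meta$stride
  res <- gconv_bwd(cache$x, d, cache$Wm, dout, k, s, cache$pad$left,
                   cache$pad$Lout)
  dWm <- res$dW
  dim(dWm) <- c(Min, k, Mout, d[1])
  dW <- aperm(dWm, c(2, 1, 3, 4))
  list(dx = res$dx, grads = list(W = dW, b = res$db))
}

# ----------------------------------------------------------- regular conv

# Ablation variant: a standard convolution with the same 1 x k kernel and
# stride, shared across EEG channels. params: W (k x Min x Mout), b (Mout).
regular_conv_forward <- function(layer, x) {
  W <- layer$params$W; b <- layer$params$b
  k <- dim(W)[1]; Min <- dim(W)[2]; Mout <- dim(W)[3]
  d <- dim(x); C <- d[1]; L <- d[3]
  s <- layer$meta$stride
  p <- .same_pad(L, k, s)
  Wm <- aperm(W, c(2, 1, 3))
  Wrep <- array(Wm, c(Min * k, Mout, C))        # shared across channels
  out <- gconv_fwd(x, d, Wrep, matrix(b, Mout, C), k, s, p$left, p$Lout)
  list(layer = layer, out = out,
       cache = list(x = x, Wrep = Wrep, dims = d, pad = p))
}

regular_conv_backward <- function(layer, dout, cache) {
  W <- layer$params$W
  k <- dim(W)[1]; Min <- dim(W)[2]; Mout <- dim(W)[3]
  d <- cache$dims
  s <- layer$meta$stride
  res <- gconv_bwd(cache$x, d, cache$Wrep, dout, k, s, cache$pad$left,
                   cache$pad$Lout)
  dWm <- rowSums(res$dW, dims = 2L)             # shared kernel: sum over C
  dim(dWm) <- c(Min, k, Mout)
  dW <- aperm(dWm, c(2, 1, 3))
  list(dx = res$dx, grads = list(W = dW, b = rowSums(res$db)))
}

# ------------------------------------------------------------ activations

leaky_relu_forward <- function(layer, x) {
  a <- layer$meta$slope
  pos <- x > 0
  out <- x * (a + (1 - a) * pos)
  list(layer = layer, out = out, cache = list(pos = pos))
}
leaky_relu_backward <- function(layer, dout, cache) {
  a <- layer$meta$slope
  list(dx = dout * (a + (1 - a) * cache$pos), grads = list())
}

elu_forward <- function(layer, x) {
  out <- x
  neg <- which(x <= 0)
  out[neg] <- expm1(x[neg])
  list(layer = layer, out = out, cache = list(out = out, neg = neg))
}
elu_backward <- function(layer, dout, cache) {
  dx <- dout
  dx[cache$neg] <- dout[cache$neg] * (cache$out[cache$neg] + 1)
  list(dx = dx, grads = list())
}

# --------------------------------------------------------------- dropout

dropout_forward <- function(layer, x, training) {
  rate <- layer$meta$rate
  if (!training || rate <= 0)
    return(list(layer = layer, out = x, cache = list(mask = NULL)))
  mask <- array(stats::runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(layer = layer, out = x * mask, cache = list(mask = mask))
}
dropout_backward <- function(layer, dout, cache) {
  dx <- if (is.null(cache$mask)) dout else dout * cache$mask
  list(dx = dx, grads = list())
}

# -------------------------------------------------------------- batchnorm

# Normalises per feature map over all remaining axes. meta$map_axis = 2
# for cubes (C, M, L, B) (each map owns C interleaved rows), 1 for
# collapsed stages (M, L, B). Population variance in-batch; running
# statistics with momentum for evaluation mode. The cube case is handled
# as an (C*M) x (L*B) matrix with per-map statistics reduced over the C
# sub-rows, avoiding any permutation of the data.
.bn_reps <- function(x, map_axis) {
  d <- dim(x)
  if (map_axis == 1L) list(r = 1L, M = d[1], N = prod(d[-1]))
  else list(r = d[1], M = d[2], N = prod(d[-(1:2)]))
}

batchnorm_forward <- function(layer, x, training) {
  info <- .bn_reps(x, layer$meta$map_axis)
  r <- info$r; M <- info$M
  d <- dim(x)
  xm <- x; dim(xm) <- c(r * M, info$N)
  per_map <- function(mat) colSums(matrix(rowSums(mat), r, M)) / (r * info$N)
  if (training) {
    mu <- per_map(xm)
    v <- per_map(xm * xm) - mu^2
    mom <- layer$meta$momentum
    layer$buffers$run_mean <- (1 - mom) * layer$buffers$run_mean + mom * mu
    layer$buffers$run_var <- (1 - mom) * layer$buffers$run_var + mom * v
  } else {
    mu <- layer$buffers$run_mean
    v <- layer$buffers$run_var
  }
  inv_sd <- 1 / sqrt(v + layer$meta$eps)
  Xh <- (xm - rep(mu, each = r)) * rep(inv_sd, each = r)
  out <- rep(layer$params$gamma, each = r) * Xh +
    rep(layer$params$beta, each = r)
  dim(out) <- d
  list(layer = layer, out = out,
       cache = list(Xh = Xh, inv_sd = inv_sd, info = info, d = d,
                    training = training))
}

batchnorm_backward <- function(layer, dout, cache) {
  info <- cache$info; r <- info$r; M <- info$M
  dY <- dout; dim(dY) <- c(r * M, info$N)
  Xh <- cache$Xh
  per_map_sum <- function(mat) colSums(matrix(rowSums(mat), r, M))
  dgamma <- per_map_sum(dY * Xh)
  dbeta <- per_map_sum(dY)
  dXh <- dY * rep(layer$params$gamma, each = r)
  inv_row <- rep(cache$inv_sd, each = r)
  if (cache$training) {
    n <- r * info$N
    m1 <- rep(per_map_sum(dXh) / n, each = r)
    m2 <- rep(per_map_sum(dXh * Xh) / n, each = r)
    dXm <- inv_row * (dXh - m1 - Xh * m2)
  } else {
    dXm <- inv_row * dXh
  }
  dim(dXm) <- cache$d
  list(dx = dXm, grads = list(gamma = dgamma, beta = dbeta))
}

# --------------------------------------------- depth-wise spatial conv

# params: W (C x M), b (M). Collapses the electrode axis with one C x 1
# kernel per feature map (VALID padding): out[m, l, b] =
# sum_c W[c, m] * x[c, m, l, b] + b[m]. Input (C, M, L, B) -> (M, L, B).
spatial_conv_forward <- function(layer, x) {
  W <- layer$params$W; b <- layer$params$b
  out <- colSums(x * as.vector(W), dims = 1L)          # (M, L, B)
  out <- out + b                                       # recycles over M
  list(layer = layer, out = out, cache = list(x = x))
}

spatial_conv_backward <- function(layer, dout, cache) {
  W <- layer$params$W
  x <- cache$x
  d <- dim(x); C <- d[1]; M <- d[2]
  dexp <- array(rep(as.vector(dout), each = C), dim = d)
  dW <- rowSums(x * dexp, dims = 2L)                   # (C, M)
  db <- rowSums(matrix(dout, M))
  dx <- dexp * as.vector(W)
  list(dx = dx, grads = list(W = dW, b = db))
}

# ----------------------------------------------------- point-wise conv

# params: P (Pout x M). 1 x 1 convolution mixing feature maps; bias-free
# (batch norm follows). Input (M, L, B) -> (Pout, L, B).
pointwise_conv_forward <- function(layer, x) {
  P <- layer$params$P
  d <- dim(x)
  y <- P %*% matrix(x, d[1])
  dim(y) <- c(nrow(P), d[2], d[3])
  list(layer = layer, out = y, cache = list(x = x))
}

pointwise_conv_backward <- function(layer, dout, cache) {
  P <- layer$params$P
  d <- dim(cache$x)
  dY <- matrix(dout, nrow(P))
  dP <- dY %*% t(matrix(cache$x, d[1]))
  dx <- crossprod(P, dY)
  dim(dx) <- d
  list(dx = dx, grads = list(P = dP))
}

# ---------------------------------------------------------------- dense

flatten_forward <- function(layer, x) {
  d <- dim(x)
  B <- d[length(d)]
  out <- matrix(x, prod(d[-length(d)]), B)
  list(layer = layer, out = out, cache = list(d = d))
}
flatten_backward <- function(layer, dout, cache) {
  dx <- dout
  dim(dx) <- cache$d
  list(dx = dx, grads = list())
}

# params: W (Nclass x D). Identity activation, no bias; softmax applied by
# the loss.
dense_forward <- function(layer, x) {
  list(layer = layer, out = layer$params$W %*% x, cache = list(x = x))
}
dense_backward <- function(layer, dout, cache) {
  list(dx = crossprod(layer$params$W, dout),
       grads = list(W = dout %*% t(cache$x)))
}
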