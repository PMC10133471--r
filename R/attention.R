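# EEG attention: a two-stage multiplicative gating module applied to a
# feature cube F of shape (C, M, L) — EEG channels x feature maps x
# feature length (batched internally as (C, M, L, B)).
#
# Stage 1 (EEG channel-wise attention): each map is average- and
# max-pooled along its feature-length axis, giving two C x M descriptor
# matrices. Per feature map m, one learned affine combination of the
# (avg, max) descriptor pair — shared across EEG channels within that map
# — is passed through a sigmoid, producing a gate matrix M_EC in
# (0,1)^(C x M) that scales each (channel, map) row.
#
# Stage 2 (specialized network-wise attention): the channel-refined cube
# is globally average- and max-pooled per map over (C, L); both pooled
# vectors pass through a shared one-hidden-layer MLP (weights W0, W1,
# reduction ratio r, rectifier in between, no biases), are summed
# element-wise and squashed by a sigmoid into a gate vector M_SN in
# (0,1)^M that rescales whole maps.

#' Parameters of the EEG channel-wise attention stage
#'
#' One affine combination of the (average, max) pooled descriptor pair per
#' feature map: `gate[c, m] = sigmoid(w_avg[m]*avg[c, m] +
#' w_max[m]*max[c, m] + bias[m])`.
#'
#' @param w_avg,w_max,bias Numeric vectors of length `n_maps`.
#' @return A list of class `"channel_attention_params"`.
#' @export
channel_attention_params <- function(w_avg, w_max, bias) {
  stopifnot(length(w_avg) == length(w_max), length(w_max) == length(bias))
  structure(list(w_avg = as.numeric(w_avg), w_max = as.numeric(w_max),
                 bias = as.numeric(bias)),
            class = "channel_attention_params")
}

#' Parameters of the specialized network-wise attention stage
#'
#' A shared one-hidden-layer MLP (`W0`: hidden x M, `W1`: M x hidden, no
#' biases, rectifier between) applied to both globally pooled descriptors.
#'
#' @param W0 Hidden-layer weight matrix (`n_hidden x n_maps`).
#' @param W1 Output-layer weight matrix (`n_maps x n_hidden`).
#' @return A list of class `"network_attention_params"`.
#' @export
network_attention_params <- function(W0, W1) {
  stopifnot(is.matrix(W0), is.matrix(W1), ncol(W1) == nrow(W0),
            nrow(W1) == ncol(W0))
  structure(list(W0 = W0, W1 = W1), class = "network_attention_params")
}

#' EEG channel-wise attention map of a feature cube
#'
#' Pools each feature map along its feature-length axis with both average
#' and max pooling, mixes the two pooled descriptors with one learned
#' affine combination per map, and applies a sigmoid.
#'
#' @param f Feature cube, array `(C, M, L)`.
#' @param params A [channel_attention_params()].
#' @return Gate matrix `M_EC` of dim `(C, M)` with entries in (0, 1).
#' @export
channel_attention <- function(f, params) {
  stopifnot(length(dim(f)) == 3, all(is.finite(f)), dim(f)[3] >= 1,
            inherits(params, "channel_attention_params"))
  C <- dim(f)[1]; M <- dim(f)[2]
  avg <- rowMeans(f, dims = 2L)                      # (C, M)
  mx <- apply(f, c(1, 2), max)
  pre <- sweep(avg, 2L, params$w_avg, `*`) +
    sweep(mx, 2L, params$w_max, `*`)
  pre <- sweep(pre, 2L, params$bias, `+`)
  sigmoid(pre)
}

#' Apply an EEG channel-wise attention map
#'
#' `f2[c, m, ] = m_ec[c, m] * f[c, m, ]`; the gate broadcasts along the
#' feature-length axis, so the refinement is element-wise contractive when
#' gates lie in (0, 1).
#'
#' @param f Feature cube `(C, M, L)`.
#' @param m_ec Gate matrix `(C, M)`.
#' @return The refined cube, same shape as `f`.
#' @export
apply_channel_attention <- function(f, m_ec) {
  stopifnot(length(dim(f)) == 3, all(dim(f)[1:2] == dim(m_ec)))
  f * as.vector(m_ec)                                # recycles over (C, M)
}

#' Specialized network-wise attention vector of a refined cube
#'
#' Globally average- and max-pools each feature map over channels and
#' feature length, passes both descriptors through the shared MLP, sums
#' element-wise and applies a sigmoid.
#'
#' @param f_prime Channel-refined feature cube `(C, M, L)`.
#' @param params A [network_attention_params()].
#' @return Gate vector `M_SN` of length `M` with entries in (0, 1).
#' @export
network_attention <- function(f_prime, params) {
  stopifnot(length(dim(f_prime)) == 3, all(is.finite(f_prime)),
            inherits(params, "network_attention_params"))
  M <- dim(f_prime)[2]
  stopifnot(ncol(params$W0) == M)
  s_avg <- apply(f_prime, 2L, mean)
  s_max <- apply(f_prime, 2L, max)
  mlp <- function(s) as.numeric(params$W1 %*% pmax(params$W0 %*% s, 0))
  sigmoid(mlp(s_avg) + mlp(s_max))
}

#' Apply a network-wise attention vector
#'
#' `f2[, m, ] = m_sn[m] * f_prime[, m, ]`.
#'
#' @param f_prime Feature cube `(C, M, L)`.
#' @param m_sn Gate vector of length `M`.
#' @return The rescaled cube, same shape as `f_prime`.
#' @export
apply_network_attention <- function(f_prime, m_sn) {
  stopifnot(length(dim(f_prime)) == 3, dim(f_prime)[2] == length(m_sn))
  C <- dim(f_prime)[1]
  f_prime * rep(m_sn, each = C)                      # recycles over (C, M)
}

#' Run the full EEG attention module on one feature cube
#'
#' Convenience composition of both stages; also returns the gates for
#' inspection (the channel-wise map reads out which electrodes each
#' feature map attends to).
#'
#' @param f Feature cube `(C, M, L)`.
#' @param ch_params A [channel_attention_params()].
#' @param net_params A [network_attention_params()].
#' @return List with `out` (refined cube), `m_ec` (`C x M`), `m_sn`
#'   (length `M`).
#' @export
eeg_attention <- function(f, ch_params, net_params) {
  m_ec <- channel_attention(f, ch_params)
  f_prime <- apply_channel_attention(f, m_ec)
  m_sn <- network_attention(f_prime, net_params)
  list(out = apply_network_attention(f_prime, m_sn), m_ec = m_ec, m_sn = m_sn)
}

# ------------------------------------------------- batched attention layer
#
# params: wa, wb, bb (length M), W0 (H x M), W1 (M x H).
# meta: channel_on, network_on. Input/output (C, M, L, B).
#
# The batched implementation never permutes whole cubes: gates are
# applied per batch element on an (C*M, L) matrix view, and pooled
# reductions accumulate over the length axis slice by slice.

.pool_len <- function(x) {
  # x: (C, M, L, B) -> avg, max and argmax over L, each as (C*M, B)
  d <- dim(x)
  CM <- d[1] * d[2]; L <- d[3]; B <- d[4]
  Xr <- x; dim(Xr) <- c(CM, L, B)
  acc <- matrix(Xr[, 1L, ], CM, B)
  mx <- acc
  am <- matrix(1L, CM, B)
  if (L > 1L) for (l in 2:L) {
    xi <- matrix(Xr[, l, ], CM, B)
    acc <- acc + xi
    upd <- xi > mx
    mx[upd] <- xi[upd]
    am[upd] <- l
  }
  list(avg = acc / L, max = mx, argmax = am)
}

.pool_global <- function(x) {
  # x: (C, M, L, B) -> avg, max and argmax over (C, L), each (M, B);
  # the argmax is returned as channel (c0) and position (l0) matrices
  d <- dim(x)
  C <- d[1]; M <- d[2]; L <- d[3]; B <- d[4]
  p1 <- .pool_len(x)                     # over L per (c, m, b)
  avg <- matrix(colSums(matrix(p1$avg, C, M * B)) / C, M, B)
  mx1 <- p1$max; dim(mx1) <- c(C, M, B)
  am1 <- p1$argmax; dim(am1) <- c(C, M, B)
  mx <- matrix(mx1[1, , ], M, B)
  c0 <- matrix(1L, M, B)
  if (C > 1L) for (cc in 2:C) {
    xi <- matrix(mx1[cc, , ], M, B)
    upd <- xi > mx
    mx[upd] <- xi[upd]
    c0[upd] <- cc
  }
  mb <- seq_len(M * B)
  m_i <- (mb - 1L) %% M + 1L
  b_i <- (mb - 1L) %/% M + 1L
  l0 <- matrix(am1[cbind(as.vector(c0), m_i, b_i)], M, B)
  list(avg = avg, max = mx, c0 = c0, l0 = l0)
}

# multiply / add a per-(channel, map) or per-map gate into a cube,
# batch element by batch element (contiguous slices, no permutation)
.mul_gate_cm <- function(x, G) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3], d[4])
  for (b in seq_len(d[4])) xm[, , b] <- xm[, , b] * G[, b]
  dim(xm) <- d
  xm
}
.add_gate_cm <- function(x, G) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3], d[4])
  for (b in seq_len(d[4])) xm[, , b] <- xm[, , b] + G[, b]
  dim(xm) <- d
  xm
}
.mul_gate_m <- function(x, g) {
  d <- dim(x); C <- d[1]
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3], d[4])
  for (b in seq_len(d[4])) xm[, , b] <- xm[, , b] * rep(g[, b], each = C)
  dim(xm) <- d
  xm
}
.add_gate_m <- function(x, g) {
  d <- dim(x); C <- d[1]
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3], d[4])
  for (b in seq_len(d[4])) xm[, , b] <- xm[, , b] + rep(g[, b], each = C)
  dim(xm) <- d
  xm
}

# sum a cube over (C, L) per (m, b): (C, M, L, B) -> (M, B)
.reduce_cl <- function(x) {
  s <- colSums(x, dims = 1L)             # (M, L, B)
  d <- dim(s)
  acc <- matrix(s[, 1L, ], d[1], d[3])
  if (d[2] > 1L) for (l in 2:d[2]) acc <- acc + matrix(s[, l, ], d[1], d[3])
  acc
}

# sum a cube over L per (c, m, b): (C, M, L, B) -> (C*M, B)
.reduce_l <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3], d[4])
  acc <- matrix(xm[, 1L, ], d[1] * d[2], d[4])
  if (d[3] > 1L) for (l in 2:d[3])
    acc <- acc + matrix(xm[, l, ], d[1] * d[2], d[4])
  acc
}

# scatter-add per-map values onto the (c0, l0) argmax entries of a cube
.scatter_max_m <- function(x, vals, c0, l0) {
  d <- dim(x); C <- d[1]; M <- d[2]; L <- d[3]; B <- d[4]
  mb <- seq_len(M * B)
  m_i <- (mb - 1L) %% M + 1L
  b_i <- (mb - 1L) %/% M + 1L
  lin <- as.vector(c0) + (m_i - 1L) * C +
    (as.vector(l0) - 1L) * C * M + (b_i - 1L) * C * M * L
  x[lin] <- x[lin] + as.vector(vals)
  x
}

attention_layer_forward <- function(layer, x) {
  d <- dim(x); C <- d[1]
  cache <- list(dims = d)
  cur <- x
  if (layer$meta$channel_on) {
    p <- .pool_len(cur)
    wa <- rep(layer$params$wa, each = C)               # length C*M
    wb <- rep(layer$params$wb, each = C)
    bb <- rep(layer$params$bb, each = C)
    pre <- p$avg * wa + p$max * wb + bb                # (CM, B)
    G <- sigmoid(pre)
    cache$ch <- list(x = cur, pool = p, G = G)
    cur <- .mul_gate_cm(cur, G)
  }
  if (layer$meta$network_on) {
    p2 <- .pool_global(cur)
    W0 <- layer$params$W0; W1 <- layer$params$W1
    h_avg_pre <- W0 %*% p2$avg; h_avg <- pmax(h_avg_pre, 0)
    h_max_pre <- W0 %*% p2$max; h_max <- pmax(h_max_pre, 0)
    pre2 <- W1 %*% h_avg + W1 %*% h_max                # (M, B)
    g2 <- sigmoid(pre2)
    cache$net <- list(fp = cur, pool = p2, g2 = g2,
                      h_avg = h_avg, h_max = h_max,
                      h_avg_pos = h_avg_pre > 0, h_max_pos = h_max_pre > 0)
    cur <- .mul_gate_m(cur, g2)
  }
  list(layer = layer, out = cur, cache = cache)
}

attention_layer_backward <- function(layer, dout, cache) {
  d <- cache$dims; C <- d[1]; M <- d[2]; L <- d[3]
  grads <- list()
  dcur <- dout
  if (layer$meta$network_on) {
    net <- cache$net
    # gate gradient: sum of dout * fp over (C, L) per (m, b)
    dg2 <- .reduce_cl(dcur * net$fp)
    dcur <- .mul_gate_m(dcur, net$g2)
    dpre2 <- dg2 * net$g2 * (1 - net$g2)
    W0 <- layer$params$W0; W1 <- layer$params$W1
    dW1 <- dpre2 %*% t(net$h_avg) + dpre2 %*% t(net$h_max)
    dh_avg <- (crossprod(W1, dpre2)) * net$h_avg_pos
    dh_max <- (crossprod(W1, dpre2)) * net$h_max_pos
    dW0 <- dh_avg %*% t(net$pool$avg) + dh_max %*% t(net$pool$max)
    ds_avg <- crossprod(W0, dh_avg)                    # (M, B)
    ds_max <- crossprod(W0, dh_max)
    grads$W0 <- dW0; grads$W1 <- dW1
    # avg pooling spreads uniformly over (C, L); max routes to argmax
    dcur <- .add_gate_m(dcur, ds_avg / (C * L))
    dcur <- .scatter_max_m(dcur, ds_max, net$pool$c0, net$pool$l0)
  }
  if (layer$meta$channel_on) {
    ch <- cache$ch
    G <- ch$G                                          # (CM, B)
    dG <- .reduce_l(dcur * ch$x)
    dcur <- .mul_gate_cm(dcur, G)
    dpre <- dG * G * (1 - G)                           # (CM, B)
    # reduce over channels within each map for the parameter gradients
    red <- function(mat) {                             # (CM, B) -> (M)
      dim(mat) <- c(C, length(mat) / C)
      rowSums(matrix(colSums(mat), M))
    }
    grads$wa <- red(dpre * ch$pool$avg)
    grads$wb <- red(dpre * ch$pool$max)
    grads$bb <- red(dpre)
    wa <- rep(layer$params$wa, each = C)
    wb <- rep(layer$params$wb, each = C)
    davg <- dpre * wa                                  # (CM, B)
    dmaxp <- dpre * wb
    # avg pool over L spreads uniformly; max routes to the argmax sample
    dcur <- .add_gate_cm(dcur, davg / L)
    CM <- C * M
    B <- d[4]
    lin <- rep(seq_len(CM), B) + (as.vector(ch$pool$argmax) - 1L) * CM +
      rep(seq_len(B) - 1L, each = CM) * CM * L
    dcur[lin] <- dcur[lin] + as.vector(dmaxp)
  }
  list(dx = dcur, grads = grads)
}

# ------------------------------------------------------------- CBAM layer
#
# Published channel-then-spatial attention block used as an ablation
# substitute for EEG attention: a per-map gate from globally pooled
# descriptors through a shared MLP (reduction ratio r), followed by a
# spatial gate from map-pooled (avg, max) planes convolved along the
# temporal axis with a length-7 kernel (SAME padding).
# params: W0 (H x M), W1 (M x H), Wsa (7), Wsm (7), bs (1).

cbam_layer_forward <- function(layer, x) {
  d <- dim(x); C <- d[1]; M <- d[2]; L <- d[3]; B <- d[4]
  cache <- list(dims = d)
  # stage 1: map-wise gate (CBAM "channel attention" over feature maps)
  p1 <- .pool_global(x)
  W0 <- layer$params$W0; W1 <- layer$params$W1
  h_avg_pre <- W0 %*% p1$avg; h_avg <- pmax(h_avg_pre, 0)
  h_max_pre <- W0 %*% p1$max; h_max <- pmax(h_max_pre, 0)
  g1 <- sigmoid(W1 %*% h_avg + W1 %*% h_max)           # (M, B)
  x1 <- .mul_gate_m(x, g1)
  cache$st1 <- list(x = x, pool = p1, g1 = g1, h_avg = h_avg, h_max = h_max,
                    h_avg_pos = h_avg_pre > 0, h_max_pos = h_max_pre > 0)
  # stage 2: spatial gate over the (C, L) plane from map-pooled planes
  pavg <- colMeans(aperm(x1, c(2, 1, 3, 4)))           # (C, L, B)
  dim(pavg) <- c(C, L, B)
  pmaxv <- array(x1[, 1, , ], c(C, L, B))
  amax <- array(1L, c(C, L, B))
  if (M > 1L) for (m in 2:M) {
    xi <- array(x1[, m, , ], c(C, L, B))
    upd <- xi > pmaxv
    pmaxv[upd] <- xi[upd]
    amax[upd] <- m
  }
  k <- length(layer$params$Wsa)
  pad <- (k - 1L) %/% 2L
  pa <- array(0, c(C, L + 2L * pad, B)); pa[, pad + seq_len(L), ] <- pavg
  pm <- array(0, c(C, L + 2L * pad, B)); pm[, pad + seq_len(L), ] <- pmaxv
  pre <- array(layer$params$bs, c(C, L, B))
  for (q in seq_len(k)) {
    idx <- q:(q + L - 1L)
    pre <- pre + layer$params$Wsa[q] * pa[, idx, ] +
      layer$params$Wsm[q] * pm[, idx, ]
  }
  g2 <- sigmoid(pre)                                   # (C, L, B)
  g2exp <- aperm(array(g2, c(C, L, B, M)), c(1, 4, 2, 3))
  out <- x1 * g2exp
  cache$st2 <- list(x1 = x1, pavg = pavg, pmax = pmaxv, amax = amax,
                    pa = pa, pm = pm, g2 = g2, pad = pad)
  list(layer = layer, out = out, cache = cache)
}

cbam_layer_backward <- function(layer, dout, cache) {
  d <- cache$dims; C <- d[1]; M <- d[2]; L <- d[3]; B <- d[4]
  st2 <- cache$st2; st1 <- cache$st1
  k <- length(layer$params$Wsa); pad <- st2$pad
  g2exp <- aperm(array(st2$g2, c(C, L, B, M)), c(1, 4, 2, 3))
  dg2 <- rowSums(aperm(dout * st2$x1, c(1, 3, 4, 2)), dims = 3L) # (C, L, B)
  dx1 <- dout * g2exp
  dpre <- dg2 * st2$g2 * (1 - st2$g2)                  # (C, L, B)
  dWsa <- numeric(k); dWsm <- numeric(k)
  dpa <- array(0, dim(st2$pa)); dpm <- array(0, dim(st2$pm))
  for (q in seq_len(k)) {
    idx <- q:(q + L - 1L)
    dWsa[q] <- sum(dpre * st2$pa[, idx, ])
    dWsm[q] <- sum(dpre * st2$pm[, idx, ])
    dpa[, idx, ] <- dpa[, idx, ] + layer$params$Wsa[q] * dpre
    dpm[, idx, ] <- dpm[, idx, ] + layer$params$Wsm[q] * dpre
  }
  dbs <- sum(dpre)
  dpavg <- dpa[, pad + seq_len(L), , drop = FALSE]
  dpmax <- dpm[, pad + seq_len(L), , drop = FALSE]
  # spread avg over maps; route max to argmax map
  dx1 <- dx1 + aperm(array(dpavg / M, c(C, L, B, M)), c(1, 4, 2, 3))
  ci <- rep(seq_len(C), times = L * B)
  li <- rep(rep(seq_len(L), each = C), times = B)
  bi <- rep(seq_len(B), each = C * L)
  lin <- ci + (as.vector(st2$amax) - 1L) * C + (li - 1L) * C * M +
    (bi - 1L) * C * M * L
  add <- numeric(C * M * L * B)
  add[lin] <- as.vector(dpmax)
  dx1 <- dx1 + array(add, c(C, M, L, B))
  # stage-1 backward (same structure as network attention)
  dg1 <- .reduce_cl(dx1 * st1$x)
  dx <- .mul_gate_m(dx1, st1$g1)
  dpre1 <- dg1 * st1$g1 * (1 - st1$g1)
  W0 <- layer$params$W0; W1 <- layer$params$W1
  dW1 <- dpre1 %*% t(st1$h_avg) + dpre1 %*% t(st1$h_max)
  dh_avg <- crossprod(W1, dpre1) * st1$h_avg_pos
  dh_max <- crossprod(W1, dpre1) * st1$h_max_pos
  dW0 <- dh_avg %*% t(st1$pool$avg) + dh_max %*% t(st1$pool$max)
  ds_avg <- crossprod(W0, dh_avg)
  ds_max <- crossprod(W0, dh_max)
  dx <- .add_gate_m(dx, ds_avg / (C * L))
  dx <- .scatter_max_m(dx, ds_max, st1$pool$c0, st1$pool$l0)
  list(dx = dx, grads = list(W0 = dW0, W1 = dW1, Wsa = dWsa, Wsm = dWsm,
                             bs = dbs))
}
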