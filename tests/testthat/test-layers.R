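# internal layer operations against brute-force oracles
fwd <- gdneteeg:::.layer_forward
bwd <- gdneteeg:::.layer_backward
nl <- gdneteeg:::new_layer

test_that("temporal convolution matches the nested-loop oracle", {
  set.seed(1)
  x <- array(rnorm(3 * 10 * 2), c(3, 10, 2))
  W <- matrix(rnorm(5 * 4), 5, 4)
  lay <- nl("temporal_conv", params = list(W = W))
  out <- fwd(lay, x, FALSE)$out
  expect_equal(dim(out), c(3, 4, 10, 2))
  expect_lt(max(abs(out - oracle_temporal_conv(x, W))), 1e-10)
})

test_that("a delta kernel reproduces the input row; zero input gives zeros", {
  x <- array(rnorm(1 * 8 * 1), c(1, 8, 1))
  W <- matrix(0, 5, 1); W[3, 1] <- 1            # centred delta
  lay <- nl("temporal_conv", params = list(W = W))
  out <- fwd(lay, x, FALSE)$out
  expect_equal(out[1, 1, , 1], x[1, , 1])
  z <- array(0, c(2, 6, 1))
  lay2 <- nl("temporal_conv", params = list(W = matrix(rnorm(10), 5, 2)))
  expect_true(all(fwd(lay2, z, FALSE)$out == 0))
})

test_that("group depth-wise convolution matches the brute-force oracle", {
  set.seed(2)
  C <- 2; Min <- 2; Mout <- 3; L <- 9; B <- 2; k <- 5
  x <- array(rnorm(C * Min * L * B), c(C, Min, L, B))
  W <- array(rnorm(k * Min * Mout * C), c(k, Min, Mout, C))
  b <- matrix(rnorm(Mout * C), Mout, C)
  lay <- nl("group_conv", params = list(W = W, b = b),
            meta = list(stride = 2L))
  out <- fwd(lay, x, FALSE)$out
  expect_equal(dim(out), c(C, Mout, ceiling(L / 2), B))
  expect_lt(max(abs(out - oracle_group_conv(x, W, b, 2))), 1e-5)
})

test_that("group blocks halve length with ceiling semantics (50 -> 25,13,7,4)", {
  lens <- 50
  for (i in 1:4) lens <- c(lens, ceiling(lens[length(lens)] / 2))
  expect_equal(lens[-1], c(25, 13, 7, 4))
  x <- array(rnorm(2 * 3 * 50), c(2, 3, 50, 1))
  L <- 50
  for (i in 1:4) {
    W <- array(rnorm(17 * 3 * 3 * 2), c(17, 3, 3, 2))
    lay <- nl("group_conv", params = list(W = W, b = matrix(0, 3, 2)),
              meta = list(stride = 2L))
    x <- fwd(lay, x, FALSE)$out
    L <- ceiling(L / 2)
    expect_equal(dim(x)[3], L)
  }
  expect_equal(dim(x)[3], 4)
})

test_that("all-zero kernels and biases give an all-zero group block output", {
  x <- array(rnorm(2 * 2 * 8), c(2, 2, 8, 1))
  lay <- nl("group_conv",
            params = list(W = array(0, c(5, 2, 2, 2)), b = matrix(0, 2, 2)),
            meta = list(stride = 2L))
  expect_true(all(fwd(lay, x, FALSE)$out == 0))
})

test_that("group convolution is equivariant to channel permutation", {
  set.seed(3)
  C <- 4
  x <- array(rnorm(C * 2 * 10 * 2), c(C, 2, 10, 2))
  W <- array(rnorm(5 * 2 * 3 * C), c(5, 2, 3, C))
  b <- matrix(rnorm(3 * C), 3, C)
  perm <- c(3, 1, 4, 2)
  lay <- nl("group_conv", params = list(W = W, b = b),
            meta = list(stride = 2L))
  out <- fwd(lay, x, FALSE)$out
  lay_p <- nl("group_conv",
              params = list(W = W[, , , perm], b = b[, perm]),
              meta = list(stride = 2L))
  out_p <- fwd(lay_p, x[perm, , , , drop = FALSE], FALSE)$out
  expect_equal(out_p, out[perm, , , , drop = FALSE])
})

test_that("the spatial depth-wise stage matches its oracle and selects channels", {
  set.seed(4)
  x <- array(rnorm(3 * 4 * 6 * 2), c(3, 4, 6, 2))
  W <- matrix(rnorm(12), 3, 4); b <- rnorm(4)
  lay <- nl("spatial_conv", params = list(W = W, b = b))
  out <- fwd(lay, x, FALSE)$out
  expect_equal(dim(out), c(4, 6, 2))
  expect_lt(max(abs(out - oracle_spatial_conv(x, W, b))), 1e-10)
  # one-hot spatial kernel selects a channel row per map
  W1 <- matrix(0, 3, 4); W1[2, ] <- 1
  lay1 <- nl("spatial_conv", params = list(W = W1, b = rep(0, 4)))
  out1 <- fwd(lay1, x, FALSE)$out
  expect_equal(out1[3, , 1], x[2, 3, , 1])
})

test_that("point-wise mixing is an exact matrix product over maps", {
  set.seed(5)
  x <- array(rnorm(4 * 5 * 2), c(4, 5, 2))
  P <- matrix(rnorm(8), 2, 4)
  lay <- nl("pointwise_conv", params = list(P = P))
  out <- fwd(lay, x, FALSE)$out
  expect_equal(dim(out), c(2, 5, 2))
  expect_equal(out[, 3, 2], as.numeric(P %*% x[, 3, 2]))
})

test_that("batch norm normalises per map and backpropagates exactly", {
  set.seed(6)
  x <- array(rnorm(3 * 4 * 5 * 6, mean = 2, sd = 3), c(3, 4, 5, 6))
  lay <- nl("batchnorm",
            params = list(gamma = rep(1, 4), beta = rep(0, 4)),
            buffers = list(run_mean = rep(0, 4), run_var = rep(1, 4)),
            meta = list(map_axis = 2L, momentum = 0.1, eps = 1e-5))
  res <- fwd(lay, x, TRUE)
  for (m in 1:4) {
    v <- res$out[, m, , ]
    expect_lt(abs(mean(v)), 1e-10)
    expect_equal(mean(v^2), 1, tolerance = 1e-3)   # eps-deflated variance
  }
  # eval mode uses running statistics, not batch statistics
  res2 <- fwd(res$layer, x, FALSE)
  expect_gt(abs(mean(res2$out[, 1, , ])), 1e-6)
})

test_that("softmax columns are probabilities; closed forms hold", {
  z <- matrix(rnorm(40 * 7), 40, 7)
  p <- softmax_columns(z)
  expect_true(all(p >= 0))
  expect_equal(colSums(p), rep(1, 7), tolerance = 1e-12)
  # zero logits (zero dense weights): uniform 1/Nclass
  expect_equal(softmax_columns(matrix(0, 40, 1))[, 1], rep(1 / 40, 40))
  # logits (1, 0) -> (e, 1) / (e + 1)
  expect_equal(softmax_columns(matrix(c(1, 0), 2, 1))[, 1],
               c(exp(1), 1) / (exp(1) + 1))
})

test_that("every layer's backward pass matches numerical gradients", {
  set.seed(7)
  cfg <- gdnet_config(n_channels = 3, n_classes = 4, n_feature_maps = 6,
                      n_group_blocks = 2, dropout_rate = 0,
                      pointwise_maps = 3, attention_reduction = 2)
  m <- init_weights(build_model(cfg, 12), seed = 7)
  B <- 4
  x <- array(rnorm(3 * 12 * B), c(3, 12, B))
  Y <- one_hot(sample(0:3, B, replace = TRUE), 4)
  fw <- model_forward(m, x, training = TRUE, keep_caches = TRUE)
  gf <- gdneteeg:::.flatten_grads(model_backward(m, fw, Y, 0.001))
  params <- model_params(m)
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(2, length(params[[nm]])))) {
      num <- numeric_grad(m, x, Y, 0.001, nm, i)
      ana <- gf[[nm]][i]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-6), 1e-4)
    }
  }
})
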