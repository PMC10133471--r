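test_that("forward shapes conform to the architecture table for (64, 250) and (64, 50)", {
  cfg <- gdnet_config(64, 40)
  for (ns in c(250L, 50L)) {
    m <- build_model(cfg, ns)
    sh <- model_shapes(m)
    # temporal conv: (C, Ns, 64) in our (C, M, L) layout
    expect_equal(sh$shape[sh$type == "temporal_conv"],
                 sprintf("64x64x%dx1", ns))
    # four halvings with ceiling semantics: 250 -> 16 (= Ns/16), 50 -> 4
    lens <- Reduce(function(l, i) ceiling(l / 2), 1:4, accumulate = TRUE,
                   init = ns)[-1]
    gshapes <- sh$shape[sh$type == "group_conv"]
    expect_equal(gshapes, sprintf("64x64x%dx1", lens))
    final <- lens[4]
    if (ns == 250) expect_equal(final, 16)   # the idealized Ns / 16
    # spatial collapse to (1, L, 64): stored as (64, L, 1)
    expect_equal(sh$shape[sh$type == "spatial_conv"],
                 sprintf("64x%dx1", final))
    # point-wise down to 16 maps
    expect_equal(sh$shape[sh$type == "pointwise_conv"],
                 sprintf("16x%dx1", final))
    expect_equal(sh$shape[nrow(sh)], "40x1")
  }
})

test_that("a full forward pass yields class probabilities over 40 targets", {
  cfg <- gdnet_config(64, 40, n_feature_maps = 8, attention_reduction = 4)
  m <- init_weights(build_model(cfg, 50), seed = 1)
  x <- array(rnorm(64 * 50 * 3), c(64, 50, 3))
  fw <- model_forward(m, x)
  expect_equal(dim(fw$probs), c(40, 3))
  expect_equal(colSums(fw$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(fw$probs >= 0))
})

test_that("disabling attention preserves all intermediate shapes", {
  on <- gdnet_config(8, 5, n_feature_maps = 8, n_group_blocks = 2)
  off <- gdnet_config(8, 5, n_feature_maps = 8, n_group_blocks = 2,
                      channel_attention = FALSE, network_attention = FALSE)
  sh_on <- model_shapes(build_model(on, 40))
  sh_off <- model_shapes(build_model(off, 40))
  keep <- sh_on$type != "attention"
  expect_equal(sh_on$shape[keep], sh_off$shape)
})

test_that("parameter counts match the closed-form count", {
  C <- 8L; K <- 16L; k <- 17L; P <- 16L; ncls <- 8L
  cfg <- gdnet_config(C, ncls, n_feature_maps = K)
  m <- build_model(cfg, 250)
  H <- max(1L, round(K / cfg$attention_reduction))
  expect_equal(count_parameters(m),
               oracle_param_count(C, K, k, 4, P, ncls, m$final_len, H))
  # without attention
  cfg3 <- gdnet_config(C, ncls, n_feature_maps = K,
                       channel_attention = FALSE, network_attention = FALSE)
  m3 <- build_model(cfg3, 250)
  expect_equal(count_parameters(m3),
               oracle_param_count(C, K, k, 4, P, ncls, m3$final_len, H,
                                  channel_att = FALSE, network_att = FALSE))
})

test_that("variant builders implement the six ablations", {
  base <- gdnet_config(8, 5, n_feature_maps = 8, attention_reduction = 4)
  # model2: shallow, two blocks; 250 -> ceil(ceil(250/2)/2) = 63
  m2 <- build_variant("model2", base, 250)
  expect_equal(m2$final_len, 63)
  expect_equal(sum(model_summary(m2)$type == "group_conv"), 2)
  # model3: attention removed, output shape unchanged
  m3 <- build_variant("model3", base, 50)
  full <- build_model(base, 50)
  expect_equal(sum(model_summary(m3)$type == "attention"), 0)
  expect_equal(m3$final_len, full$final_len)
  expect_equal(dim(model_forward(init_weights(m3, 1),
                                 array(0, c(8, 50, 1)))$probs), c(5, 1))
  # model4 / model5: one stage each
  m4 <- build_variant("model4", base, 50)
  att4 <- Filter(function(l) l$type == "attention", m4$layers)
  expect_true(all(vapply(att4, function(l) !l$meta$channel_on, logical(1))))
  m5 <- build_variant("model5", base, 50)
  att5 <- Filter(function(l) l$type == "attention", m5$layers)
  expect_true(all(vapply(att5, function(l) !l$meta$network_on, logical(1))))
  # model1: regular convolution, more parameters than group depth-wise
  m1 <- build_variant("model1", base, 50)
  expect_gt(count_parameters(m1) * (8 > 1), 0)
  # model6: CBAM substitution still runs forward
  m6 <- init_weights(build_variant("model6", base, 50), seed = 2)
  expect_equal(dim(model_forward(m6, array(rnorm(8 * 50 * 2),
                                           c(8, 50, 2)))$probs), c(5, 2))
  expect_error(build_variant("model7", base, 50), "unknown")
})

test_that("group blocks carry C independent kernel sets vs the shared regular conv", {
  # a group depth-wise block learns one kernel per EEG channel per map
  # pair ((k*K*K + K) * C parameters), while the regular-conv variant
  # shares one kernel across channels (k*K*K + K); the whole-model
  # difference is exactly 4 blocks times that gap
  C <- 8; K <- 16; k <- 17
  group_block <- (k * K * K + K) * C
  regular_block <- k * K * K + K
  base <- gdnet_config(C, 5, n_feature_maps = K)
  n_full <- count_parameters(build_model(base, 50))
  n_m1 <- count_parameters(build_variant("model1", base, 50))
  expect_equal(n_full - n_m1, 4 * (group_block - regular_block))
  expect_gt(n_full, n_m1)
})

test_that("checkpoints round-trip with identical predictions", {
  cfg <- gdnet_config(4, 3, n_feature_maps = 4, n_group_blocks = 1,
                      attention_reduction = 4)
  m <- init_weights(build_model(cfg, 20), seed = 5)
  x <- array(rnorm(4 * 20 * 3), c(4, 20, 3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(model_forward(m, x)$probs, model_forward(m2, x)$probs)
})

test_that("input shape mismatches are rejected", {
  cfg <- gdnet_config(4, 3, n_feature_maps = 4, n_group_blocks = 1)
  m <- init_weights(build_model(cfg, 20), seed = 1)
  expect_error(model_forward(m, array(0, c(5, 20, 1))), "channels")
  expect_error(model_forward(m, array(0, c(4, 30, 1))), "samples")
  expect_error(gdnet_config(4, 3, variant_id = "modelX"), "unknown")
})
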