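# small separable fixture: two classes with strongly distinct waveforms
make_toy_segments <- function(n_per_class = 20, n = 30, C = 2, seed = 1) {
  set.seed(seed)
  B <- 2 * n_per_class
  X <- array(rnorm(C * n * B, sd = 0.1), c(C, n, B))
  y <- rep(0:1, each = n_per_class)
  tt <- seq_len(n) / n
  for (i in seq_len(B)) {
    f <- if (y[i] == 0) 3 else 8
    X[, , i] <- X[, , i] + matrix(sin(2 * pi * f * tt), C, n, byrow = TRUE)
  }
  ids <- paste0("trial", seq_len(B))
  ord <- sample(B)
  structure(list(X = X[, , ord], y = y[ord], ratio = n / 250,
                 sampling_rate = 250, source_trial_ids = ids[ord]),
            class = "segment_batch")
}

toy_model <- function(seed = 1) {
  cfg <- gdnet_config(2, 2, n_feature_maps = 4, n_group_blocks = 1,
                      dropout_rate = 0, attention_reduction = 4)
  init_weights(build_model(cfg, 30), seed = seed)
}

test_that("loss closed forms hold", {
  # perfect predictions, zero weights -> 0
  Y <- one_hot(c(0L, 1L), 2)
  expect_equal(cross_entropy_loss(Y, Y, numeric(0), 0), 0)
  # uniform prediction over 40 classes -> ln 40
  p40 <- matrix(1 / 40, 40, 3)
  y40 <- one_hot(c(0L, 5L, 39L), 40)
  expect_equal(cross_entropy_loss(p40, y40, numeric(0), 0), log(40),
               tolerance = 1e-9)
  # L2 term: w = (1, -2), lambda = 0.001 -> 0.005 on perfect predictions
  expect_equal(cross_entropy_loss(Y, Y, c(1, -2), 0.001), 0.005)
  # zero probability at the true class is clamped, not infinite
  p_bad <- matrix(c(0, 1), 2, 1)
  y_bad <- one_hot(0L, 2)
  expect_message(l <- cross_entropy_loss(p_bad, y_bad, numeric(0), 0),
                 "clamping")
  expect_true(is.finite(l))
})

test_that("the L2 term equals lambda * sum(w^2) exactly", {
  m <- toy_model(3)
  w <- decayed_weights(m)
  lam <- 0.001
  Y <- one_hot(0L, 2)
  p <- matrix(c(1, 0), 2, 1)
  expect_equal(cross_entropy_loss(p, Y, w, lam),
               lam * sum(unlist(w)^2))
  # biases and batch-norm parameters are excluded from the decayed set
  expect_false(any(grepl("\\.(b|bb|beta|gamma)$", names(w))))
})

test_that("initialisation is Gaussian(0, 0.01 variance) and deterministic", {
  cfg <- gdnet_config(8, 8, n_feature_maps = 16, n_group_blocks = 2)
  m1 <- init_weights(build_model(cfg, 50), seed = 11)
  m2 <- init_weights(build_model(cfg, 50), seed = 11)
  expect_identical(model_params(m1), model_params(m2))
  w <- unlist(decayed_weights(m1))
  expect_gt(length(w), 1e4)
  expect_lt(abs(mean(w)), 0.005)
  expect_true(stats::sd(w) > 0.095 && stats::sd(w) < 0.105)
  # biases zero, batch norm at identity
  p <- model_params(m1)
  bn <- p[grepl("gamma", names(p))]
  expect_true(all(unlist(bn) == 1))
})

test_that("training fits a separable two-class toy within 50 epochs", {
  segs <- make_toy_segments(seed = 2)
  val <- make_toy_segments(n_per_class = 5, seed = 3)
  fit <- train_model(toy_model(2), segs, val,
                     train_config(max_epochs = 50, early_stop_patience = 50,
                                  batch_size = 10, l2_lambda = 0, seed = 2))
  expect_equal(max(fit$history$train_acc), 1)
  # loss decreases over the first epochs
  expect_lt(fit$history$train_loss[3], fit$history$train_loss[1])
})

test_that("patience 0 stops after the first non-improving epoch", {
  segs <- make_toy_segments(seed = 4)
  val <- make_toy_segments(n_per_class = 5, seed = 5)
  fit <- train_model(toy_model(4), segs, val,
                     train_config(max_epochs = 50, early_stop_patience = 0,
                                  batch_size = 10, seed = 4))
  n_ep <- nrow(fit$history)
  expect_gte(n_ep, 1)
  improving <- diff(c(Inf, fit$history$val_loss)) < -1e-9
  # stopped exactly when an epoch first failed to improve (or hit max)
  if (n_ep < 50) expect_false(improving[n_ep])
  # every epoch before the last improved the validation loss
  if (n_ep > 1) expect_true(all(improving[seq_len(n_ep - 1)]))
})

test_that("fixed-seed training is bitwise reproducible", {
  segs <- make_toy_segments(seed = 6)
  val <- make_toy_segments(n_per_class = 5, seed = 7)
  cfg <- train_config(max_epochs = 5, batch_size = 10, seed = 9)
  f1 <- train_model(toy_model(6), segs, val, cfg)
  f2 <- train_model(toy_model(6), segs, val, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(model_params(f1$model), model_params(f2$model))
})

test_that("empty training data errors", {
  segs <- make_toy_segments(seed = 1)
  empty <- subset_segments(segs, integer(0))
  expect_error(train_model(toy_model(1), empty, segs, train_config()),
               "empty")
})

test_that("two-stage training starts stage 2 from stage-1 weights", {
  a <- make_toy_segments(seed = 10); av <- make_toy_segments(5, seed = 11)
  b <- make_toy_segments(seed = 12); bv <- make_toy_segments(5, seed = 13)
  cfg <- gdnet_config(2, 2, n_feature_maps = 4, n_group_blocks = 1,
                      dropout_rate = 0, attention_reduction = 4)
  model <- build_model(cfg, 30)
  tc <- train_config(max_epochs = 3, batch_size = 10, seed = 14)
  # stage2_epochs = 0: returns stage-1 weights unchanged
  r0 <- two_stage_train(model, a, av, b, bv, tc, stage2_epochs = 0)
  expect_identical(model_params(r0$model), model_params(r0$stage1$model))
  # normal stage 2 starts from the stage-1 checkpoint
  ckpt <- withr::local_tempdir()
  r <- two_stage_train(model, a, av, b, bv, tc, checkpoint_dir = ckpt)
  expect_identical(r$stage2_start, model_params(r$stage1$model))
  expect_true(file.exists(r$checkpoints$stage1))
  expect_true(file.exists(r$checkpoints$stage2))
  s1 <- load_checkpoint(r$checkpoints$stage1)
  expect_identical(model_params(s1), model_params(r$stage1$model))
  # incompatible stage data is rejected
  bad <- b; bad$X <- bad$X[1, , , drop = FALSE]
  expect_error(two_stage_train(model, a, av, bad, bv, tc), "share")
})

test_that("pre-training on related data helps the fine-tuning start", {
  # over several seeds, a stage-2 model starting from stage-1 weights has
  # lower validation loss before fine-tuning than a fresh initialisation
  wins <- 0L
  for (seed in 1:5) {
    a <- make_toy_segments(15, seed = seed)
    av <- make_toy_segments(5, seed = seed + 100)
    bv <- make_toy_segments(5, seed = seed + 300)
    cfg <- gdnet_config(2, 2, n_feature_maps = 4, n_group_blocks = 1,
                        dropout_rate = 0, attention_reduction = 4)
    tc <- train_config(max_epochs = 8, batch_size = 10, seed = seed)
    model <- init_weights(build_model(cfg, 30), seed = seed)
    s1 <- train_model(model, a, av, tc)
    warm <- gdneteeg:::.eval_batchwise(s1$model, bv, 0)$loss
    cold <- gdneteeg:::.eval_batchwise(model, bv, 0)$loss
    wins <- wins + (warm < cold)
  }
  expect_gte(wins, 4)
})
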