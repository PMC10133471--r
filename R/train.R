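#' Training configuration
#'
#' Optimisation constants: Adam at learning rate 0.001, batches of 64
#' segments, L2 regularisation constant 0.001, Gaussian initialisation
#' with mean 0 and variance 0.01, early stopping on validation loss.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size. By default counted in segments; with
#'   `batch_unit = "trials"` a batch is the segments of `batch_size`
#'   whole trials (`t x D_b` segments).
#' @param l2_lambda L2 regularisation constant `lambda`.
#' @param init_sd Standard deviation of the Gaussian weight initialisation
#'   (variance 0.01 gives sd 0.1).
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (0 stops at the first non-improving epoch).
#' @param max_epochs Maximum number of epochs.
#' @param batch_unit `"segments"` or `"trials"`.
#' @param seed RNG seed covering initialisation order, shuffling and
#'   dropout.
#' @param verbose Print per-epoch progress.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         l2_lambda = 0.001, init_sd = 0.1,
                         early_stop_patience = 10L, max_epochs = 200L,
                         batch_unit = c("segments", "trials"),
                         seed = 1L, verbose = FALSE) {
  batch_unit <- match.arg(batch_unit)
  stopifnot(learning_rate > 0, batch_size >= 1, l2_lambda >= 0, init_sd > 0,
            early_stop_patience >= 0, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), l2_lambda = l2_lambda,
                 init_sd = init_sd,
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 batch_unit = batch_unit, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Regularised categorical cross-entropy
#'
#' `-(1/N) * sum_i sum_j y_ij log(s_ij) + lambda * sum(w^2)`, where `N` is
#' the number of segments in the batch and `w` collects the model weights.
#' Probabilities at a true class that underflow to zero are clamped at a
#' small epsilon (with a message) rather than producing infinities.
#'
#' @param probs Softmax output matrix `Nclass x N` (columns sum to 1).
#' @param y_onehot One-hot target matrix, same shape.
#' @param weights Numeric vector (or list of arrays) of model weights
#'   entering the L2 term; may be empty.
#' @param lambda L2 constant.
#' @param eps Clamp for `log(0)`.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(probs, y_onehot, weights = numeric(0),
                               lambda = 0, eps = 1e-12) {
  stopifnot(all(dim(probs) == dim(y_onehot)))
  p_true <- colSums(probs * y_onehot)
  if (any(p_true < eps)) {
    message("clamping ", sum(p_true < eps),
            " zero predicted probabilities at the true class")
    p_true <- pmax(p_true, eps)
  }
  w2 <- sum(unlist(weights, use.names = FALSE)^2)
  -mean(log(p_true)) + lambda * w2
}

#' One-hot encode 0-based class labels
#'
#' @param y Integer vector of 0-based class indices.
#' @param n_classes Number of classes.
#' @return Matrix `n_classes x length(y)`.
#' @export
one_hot <- function(y, n_classes) {
  Y <- matrix(0, n_classes, length(y))
  Y[cbind(y + 1L, seq_along(y))] <- 1
  Y
}

#' Decayed (L2-regularised) weights of a model
#'
#' The multiplicative weights entering the L2 term: convolution kernels,
#' attention mixing/MLP weights and the dense matrix. Biases and
#' batch-norm scale/shift are excluded.
#'
#' @param model A `gdnet_model`.
#' @return Named list of weight arrays.
#' @export
decayed_weights <- function(model) {
  out <- list()
  for (i in seq_along(model$layers)) {
    for (nm in model$layers[[i]]$meta$decay %||% character(0))
      out[[sprintf("L%02d.%s", i, nm)]] <- model$layers[[i]]$params[[nm]]
  }
  out
}

#' Initialise model weights
#'
#' All convolution, attention and dense weights are drawn i.i.d. Gaussian
#' with mean 0 and standard deviation `sd` (variance 0.01 by default);
#' biases are zero; batch-norm scale/shift start at identity and running
#' statistics are reset. Deterministic per seed.
#'
#' @param model A `gdnet_model`.
#' @param seed Integer seed.
#' @param sd Weight standard deviation.
#' @return The initialised model.
#' @export
init_weights <- function(model, seed = 1L, sd = 0.1) {
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  for (i in seq_along(model$layers)) {
    lay <- model$layers[[i]]
    decay <- lay$meta$decay %||% character(0)
    for (nm in names(lay$params)) {
      p <- lay$params[[nm]]
      if (nm %in% decay) {
        lay$params[[nm]][] <- stats::rnorm(length(p), 0, sd)
      } else if (nm == "gamma") {
        lay$params[[nm]][] <- 1
      } else {
        lay$params[[nm]][] <- 0          # biases, beta
      }
    }
    if (lay$type == "batchnorm") {
      lay$buffers$run_mean[] <- 0
      lay$buffers$run_var[] <- 1
    }
    model$layers[[i]] <- lay
  }
  model
}

# ------------------------------------------------------------------ Adam

.adam_init <- function(params) {
  list(m = lapply(params, function(p) { p[] <- 0; p }),
       v = lapply(params, function(p) { p[] <- 0; p }),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.flatten_grads <- function(grads) {
  out <- list()
  for (i in seq_along(grads)) {
    for (nm in names(grads[[i]]))
      out[[sprintf("L%02d.%s", i, nm)]] <- grads[[i]][[nm]]
  }
  out
}

.eval_batchwise <- function(model, batch, lambda, chunk = 256L) {
  B <- length(batch$y)
  Y <- one_hot(batch$y, model$cfg$n_classes)
  loss_sum <- 0; correct <- 0L
  w <- decayed_weights(model)
  for (start in seq(1L, B, by = chunk)) {
    idx <- start:min(start + chunk - 1L, B)
    fw <- model_forward(model, batch$X[, , idx, drop = FALSE],
                        training = FALSE)
    p_true <- pmax(colSums(fw$probs * Y[, idx, drop = FALSE]), 1e-12)
    loss_sum <- loss_sum - sum(log(p_true))
    pred <- max.col(t(fw$probs), ties.method = "first") - 1L
    correct <- correct + sum(pred == batch$y[idx])
  }
  list(loss = loss_sum / B + lambda * sum(unlist(w)^2),
       acc = correct / B)
}

#' Train a model
#'
#' Mini-batch gradient descent with Adam on the regularised categorical
#' cross-entropy. After every epoch the validation loss is evaluated (in
#' evaluation mode); training stops when it has failed to improve for
#' `early_stop_patience` consecutive epochs, and the weights with the best
#' validation loss are restored.
#'
#' @param model An initialised `gdnet_model` (see [init_weights()]).
#' @param train_batch,val_batch Disjoint `segment_batch` objects.
#' @param cfg A [train_config()].
#' @return List with `model` (best weights), `history` (data frame of
#'   per-epoch train/validation loss and accuracy) and `best_epoch`.
#' @export
train_model <- function(model, train_batch, val_batch, cfg = train_config()) {
  stopifnot(inherits(model, "gdnet_model"), inherits(cfg, "train_config"))
  n <- length(train_batch$y)
  if (n == 0L) stop("empty training data", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(cfg$seed)
  params <- model_params(model)
  state <- .adam_init(params)
  Yfull <- one_hot(train_batch$y, model$cfg$n_classes)
  best_loss <- Inf; best_params <- params; best_buffers <- NULL
  best_epoch <- 0L; bad <- 0L
  hist <- data.frame()
  trial_ids <- train_batch$source_trial_ids
  for (epoch in seq_len(cfg$max_epochs)) {
    if (cfg$batch_unit == "trials") {
      # a batch is the pooled segments of batch_size whole trials
      ord_t <- sample(unique(trial_ids))
      grp_of_trial <- stats::setNames(
        ceiling(seq_along(ord_t) / cfg$batch_size), ord_t)
      groups <- split(seq_len(n), grp_of_trial[trial_ids])
    } else {
      ord <- sample.int(n)
      groups <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    }
    ep_loss <- 0; ep_correct <- 0L; ep_n <- 0L
    for (idx in groups) {
      xb <- train_batch$X[, , idx, drop = FALSE]
      yb <- Yfull[, idx, drop = FALSE]
      fw <- model_forward(model, xb, training = TRUE, keep_caches = TRUE)
      model <- fw$model
      w <- decayed_weights(model)
      loss <- cross_entropy_loss(fw$probs, yb, w, cfg$l2_lambda)
      grads <- .flatten_grads(model_backward(model, fw, yb, cfg$l2_lambda))
      params <- model_params(model)
      upd <- .adam_step(params, grads, state, cfg$learning_rate)
      model <- model_set_params(model, upd$params)
      state <- upd$state
      pred <- max.col(t(fw$probs), ties.method = "first") - 1L
      ep_correct <- ep_correct + sum(pred == train_batch$y[idx])
      ep_loss <- ep_loss + loss * length(idx)
      ep_n <- ep_n + length(idx)
    }
    val <- .eval_batchwise(model, val_batch, cfg$l2_lambda)
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = ep_loss / ep_n,
      train_acc = ep_correct / ep_n, val_loss = val$loss, val_acc = val$acc))
    if (cfg$verbose)
      message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f",
                      epoch, ep_loss / ep_n, ep_correct / ep_n,
                      val$loss, val$acc))
    if (val$loss < best_loss - 1e-9) {
      best_loss <- val$loss
      best_params <- model_params(model)
      best_buffers <- lapply(model$layers, function(l) l$buffers)
      best_epoch <- epoch
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > cfg$early_stop_patience) break
    }
  }
  if (!is.null(best_buffers)) {
    model <- model_set_params(model, best_params)
    for (i in seq_along(model$layers)) model$layers[[i]]$buffers <- best_buffers[[i]]
  }
  list(model = model, history = hist, best_epoch = best_epoch)
}

#' Two-stage transfer training
#'
#' Stage 1 trains from the Gaussian initialisation on the first dataset;
#' stage 2 re-initialises the network with the stage-1 weights and
#' fine-tunes them on the second dataset (accounting for inter-dataset
#' statistical variation). Both stage models are returned (and written to
#' disk when `checkpoint_dir` is given).
#'
#' @param model A built (not necessarily initialised) `gdnet_model`; both
#'   datasets must share channel count, segment length and class count.
#' @param stage1_train,stage1_val Stage-1 `segment_batch` pair.
#' @param stage2_train,stage2_val Stage-2 `segment_batch` pair.
#' @param cfg A [train_config()].
#' @param stage2_epochs Optional cap on stage-2 epochs (defaults to
#'   `cfg$max_epochs`); 0 returns the stage-1 weights unchanged.
#' @param checkpoint_dir Optional directory to persist both checkpoints.
#' @return List with `model` (stage-2 result), `stage1`, `stage2`
#'   (full training results) and checkpoint paths when written.
#' @export
two_stage_train <- function(model, stage1_train, stage1_val,
                            stage2_train, stage2_val, cfg = train_config(),
                            stage2_epochs = NULL, checkpoint_dir = NULL) {
  for (b in list(stage1_train, stage2_train)) {
    if (dim(b$X)[1] != model$cfg$n_channels ||
        dim(b$X)[2] != model$n_samples)
      stop("stage datasets must share the model's channel count and ",
           "segment length", call. = FALSE)
  }
  model <- init_weights(model, seed = cfg$seed, sd = cfg$init_sd)
  s1 <- train_model(model, stage1_train, stage1_val, cfg)
  paths <- list()
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    paths$stage1 <- file.path(checkpoint_dir, "stage1.rds")
    save_checkpoint(s1$model, paths$stage1)
  }
  cfg2 <- cfg
  if (!is.null(stage2_epochs)) cfg2$max_epochs <- as.integer(stage2_epochs)
  if (cfg2$max_epochs == 0L) {
    s2 <- list(model = s1$model, history = data.frame(), best_epoch = 0L)
  } else {
    s2 <- train_model(s1$model, stage2_train, stage2_val, cfg2)
  }
  if (!is.null(checkpoint_dir)) {
    paths$stage2 <- file.path(checkpoint_dir, "stage2.rds")
    save_checkpoint(s2$model, paths$stage2)
  }
  list(model = s2$model, stage1 = s1, stage2 = s2,
       stage2_start = model_params(s1$model), checkpoints = paths)
}
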