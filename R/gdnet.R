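#' Architecture configuration
#'
#' Hyperparameters of the group depth-wise convolutional network: a
#' temporal convolution (64 maps, 1 x 17 kernels, stride 1), a stack of
#' group depth-wise convolution blocks (1 x 17 kernels per EEG channel,
#' stride 2, LeakyReLU, batch norm), optional EEG attention after each
#' block, one dropout after the block stack, a depth-wise separable head
#' (C x 1 spatial collapse with ELU, then a 1 x 1 point-wise mix down to
#' 16 maps with batch norm, ELU and dropout) and a dense softmax output.
#' No pooling layers are used anywhere.
#'
#' @param n_channels Number of EEG channels `C`.
#' @param n_classes Number of stimulation frequencies `Nclass`.
#' @param n_feature_maps Feature maps `K` per convolutional stage
#'   (default 64).
#' @param kernel_length Temporal kernel length (default 17, odd).
#' @param n_group_blocks Number of group depth-wise blocks (default 4).
#' @param dropout_rate Dropout rate (default 0.5).
#' @param pointwise_maps Maps after the point-wise convolution (default 16).
#' @param channel_attention,network_attention Enable the EEG channel-wise /
#'   specialized network-wise attention stages.
#' @param attention_reduction MLP reduction ratio `r` of the network-wise
#'   stage (hidden width `max(1, round(K / r))`, default `r` = 8).
#' @param leaky_slope Negative slope of LeakyReLU (default 0.01).
#' @param bn_momentum,bn_eps Batch-normalisation running-statistics
#'   momentum and variance epsilon.
#' @param group_stride Temporal stride of the group blocks (default 2).
#' @param variant_id One of `"full"` or the ablation variants
#'   `"model1"`..`"model6"`; use [build_variant()] to derive variant
#'   configurations.
#'
#' @return A list of class `"gdnet_config"`.
#' @export
gdnet_config <- function(n_channels, n_classes, n_feature_maps = 64L,
                         kernel_length = 17L, n_group_blocks = 4L,
                         dropout_rate = 0.5, pointwise_maps = 16L,
                         channel_attention = TRUE, network_attention = TRUE,
                         attention_reduction = 8, leaky_slope = 0.01,
                         bn_momentum = 0.1, bn_eps = 1e-5,
                         group_stride = 2L, variant_id = "full") {
  stopifnot(n_channels >= 1, n_classes >= 2, n_feature_maps >= 1,
            kernel_length %% 2 == 1, n_group_blocks >= 1,
            dropout_rate >= 0, dropout_rate < 1, pointwise_maps >= 1)
  if (!variant_id %in% c("full", paste0("model", 1:6)))
    stop("unknown variant id: ", variant_id, call. = FALSE)
  if (variant_id == "model3" && (channel_attention || network_attention))
    stop("variant model3 removes both attention stages", call. = FALSE)
  structure(list(
    n_channels = as.integer(n_channels), n_classes = as.integer(n_classes),
    n_feature_maps = as.integer(n_feature_maps),
    kernel_length = as.integer(kernel_length),
    n_group_blocks = as.integer(n_group_blocks),
    dropout_rate = dropout_rate, pointwise_maps = as.integer(pointwise_maps),
    channel_attention = channel_attention,
    network_attention = network_attention,
    attention_reduction = attention_reduction, leaky_slope = leaky_slope,
    bn_momentum = bn_momentum, bn_eps = bn_eps,
    group_stride = as.integer(group_stride), variant_id = variant_id
  ), class = "gdnet_config")
}

#' Assemble the network for a given input length
#'
#' Builds the layer stack for segments of `n_samples` time points:
#' temporal convolution + batch norm, then `n_group_blocks` repetitions of
#' (group depth-wise convolution, LeakyReLU, batch norm, attention if
#' enabled), one dropout, the depth-wise separable head, and the dense
#' softmax classifier. Attention parameters are independent per block.
#' Weights are zero until [init_weights()] is called.
#'
#' @param cfg A [gdnet_config()].
#' @param n_samples Segment length in samples (`Ns`).
#' @return A list of class `"gdnet_model"` with elements `cfg`,
#'   `n_samples`, `layers` and the flattened feature size `flat_dim`.
#' @export
build_model <- function(cfg, n_samples) {
  stopifnot(inherits(cfg, "gdnet_config"), n_samples >= 1)
  C <- cfg$n_channels; K <- cfg$n_feature_maps; k <- cfg$kernel_length
  H <- max(1L, as.integer(round(K / cfg$attention_reduction)))
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l

  add(new_layer("temporal_conv", params = list(W = matrix(0, k, K)),
                meta = list(decay = "W")))
  add(.bn_layer(K, 2L, cfg))

  L <- n_samples
  for (blk in seq_len(cfg$n_group_blocks)) {
    if (cfg$variant_id == "model1") {
      add(new_layer("regular_conv",
                    params = list(W = array(0, c(k, K, K)), b = numeric(K)),
                    meta = list(stride = cfg$group_stride, decay = "W")))
    } else {
      add(new_layer("group_conv",
                    params = list(W = array(0, c(k, K, K, C)),
                                  b = matrix(0, K, C)),
                    meta = list(stride = cfg$group_stride, decay = "W")))
    }
    L <- ceiling(L / cfg$group_stride)
    add(new_layer("leaky_relu", meta = list(slope = cfg$leaky_slope)))
    add(.bn_layer(K, 2L, cfg))
    if (cfg$variant_id == "model6") {
      add(new_layer("cbam",
                    params = list(W0 = matrix(0, H, K), W1 = matrix(0, K, H),
                                  Wsa = numeric(7), Wsm = numeric(7), bs = 0),
                    meta = list(decay = c("W0", "W1", "Wsa", "Wsm"))))
    } else if (cfg$channel_attention || cfg$network_attention) {
      pars <- list(); dec <- character(0)
      if (cfg$channel_attention) {
        pars <- c(pars, list(wa = numeric(K), wb = numeric(K),
                             bb = numeric(K)))
        dec <- c(dec, "wa", "wb")
      }
      if (cfg$network_attention) {
        pars <- c(pars, list(W0 = matrix(0, H, K), W1 = matrix(0, K, H)))
        dec <- c(dec, "W0", "W1")
      }
      add(new_layer("attention", params = pars,
                    meta = list(channel_on = cfg$channel_attention,
                                network_on = cfg$network_attention,
                                decay = dec)))
    }
  }
  add(new_layer("dropout", meta = list(rate = cfg$dropout_rate)))
  add(new_layer("spatial_conv",
                params = list(W = matrix(0, C, K), b = numeric(K)),
                meta = list(decay = "W")))
  add(new_layer("elu"))
  add(new_layer("pointwise_conv",
                params = list(P = matrix(0, cfg$pointwise_maps, K)),
                meta = list(decay = "P")))
  add(.bn_layer(cfg$pointwise_maps, 1L, cfg))
  add(new_layer("elu"))
  add(new_layer("dropout", meta = list(rate = cfg$dropout_rate)))
  add(new_layer("flatten"))
  flat_dim <- cfg$pointwise_maps * L
  add(new_layer("dense",
                params = list(W = matrix(0, cfg$n_classes, flat_dim)),
                meta = list(decay = "W")))
  structure(list(cfg = cfg, n_samples = as.integer(n_samples),
                 layers = layers, flat_dim = flat_dim, final_len = L),
            class = "gdnet_model")
}

.bn_layer <- function(n_maps, map_axis, cfg) {
  new_layer("batchnorm",
            params = list(gamma = rep(1, n_maps), beta = rep(0, n_maps)),
            buffers = list(run_mean = rep(0, n_maps), run_var = rep(1, n_maps)),
            meta = list(map_axis = map_axis, momentum = cfg$bn_momentum,
                        eps = cfg$bn_eps, decay = character(0)))
}

#' Build an ablation variant
#'
#' Variants of the full architecture used to attribute performance:
#' `model1` replaces group depth-wise filters with regular convolutions of
#' equal kernel size and stride (shared across EEG channels); `model2` is
#' a shallow version with two group blocks; `model3` removes the EEG
#' attention module; `model4` removes only the channel-wise stage;
#' `model5` removes only the network-wise stage; `model6` substitutes a
#' CBAM block (shared-MLP map gate followed by a 7-tap spatial gate) for
#' EEG attention.
#'
#' @param variant_id `"full"` or `"model1"`..`"model6"`.
#' @param cfg A base [gdnet_config()] (its attention flags are overridden
#'   as the variant requires).
#' @param n_samples Segment length in samples.
#' @return A `gdnet_model`.
#' @export
build_variant <- function(variant_id, cfg, n_samples) {
  stopifnot(inherits(cfg, "gdnet_config"))
  if (!variant_id %in% c("full", paste0("model", 1:6)))
    stop("unknown variant id: ", variant_id, call. = FALSE)
  cfg$variant_id <- variant_id
  if (variant_id == "model2") cfg$n_group_blocks <- 2L
  if (variant_id == "model3") {
    cfg$channel_attention <- FALSE; cfg$network_attention <- FALSE
  }
  if (variant_id == "model4") cfg$channel_attention <- FALSE
  if (variant_id == "model5") cfg$network_attention <- FALSE
  build_model(cfg, n_samples)
}

# ------------------------------------------------------------ forward/back

.layer_forward <- function(layer, x, training) {
  switch(layer$type,
    temporal_conv  = temporal_conv_forward(layer, x),
    group_conv     = group_conv_forward(layer, x),
    regular_conv   = regular_conv_forward(layer, x),
    leaky_relu     = leaky_relu_forward(layer, x),
    elu            = elu_forward(layer, x),
    batchnorm      = batchnorm_forward(layer, x, training),
    dropout        = dropout_forward(layer, x, training),
    attention      = attention_layer_forward(layer, x),
    cbam           = cbam_layer_forward(layer, x),
    spatial_conv   = spatial_conv_forward(layer, x),
    pointwise_conv = pointwise_conv_forward(layer, x),
    flatten        = flatten_forward(layer, x),
    dense          = dense_forward(layer, x),
    stop("unknown layer type ", layer$type))
}

.layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    temporal_conv  = temporal_conv_backward(layer, dout, cache),
    group_conv     = group_conv_backward(layer, dout, cache),
    regular_conv   = regular_conv_backward(layer, dout, cache),
    leaky_relu     = leaky_relu_backward(layer, dout, cache),
    elu            = elu_backward(layer, dout, cache),
    batchnorm      = batchnorm_backward(layer, dout, cache),
    dropout        = dropout_backward(layer, dout, cache),
    attention      = attention_layer_backward(layer, dout, cache),
    cbam           = cbam_layer_backward(layer, dout, cache),
    spatial_conv   = spatial_conv_backward(layer, dout, cache),
    pointwise_conv = pointwise_conv_backward(layer, dout, cache),
    flatten        = flatten_backward(layer, dout, cache),
    dense          = dense_backward(layer, dout, cache),
    stop("unknown layer type ", layer$type))
}

#' Forward pass
#'
#' Runs a batch of segments through the network. In training mode batch
#' norm uses in-batch statistics (and updates its running buffers) and
#' dropout is active; in evaluation mode running statistics are used and
#' dropout is the identity.
#'
#' @param model A `gdnet_model`.
#' @param x Input array `(C, Ns, B)` (a `segment_batch$X`).
#' @param training Logical.
#' @param keep_caches Keep per-layer caches for a subsequent backward pass.
#' @return List with `model` (updated buffers), `logits`
#'   (`Nclass x B`), `probs` (softmax columns), and `caches` when
#'   requested.
#' @export
model_forward <- function(model, x, training = FALSE, keep_caches = FALSE) {
  stopifnot(inherits(model, "gdnet_model"), length(dim(x)) == 3)
  d <- dim(x)
  if (d[1] != model$cfg$n_channels)
    stop("input has ", d[1], " channels; model expects ",
         model$cfg$n_channels, call. = FALSE)
  if (d[2] != model$n_samples)
    stop("input has ", d[2], " samples; model built for ",
         model$n_samples, call. = FALSE)
  if (d[1] == 0 || d[2] == 0) stop("empty input", call. = FALSE)
  cur <- x
  caches <- if (keep_caches) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    res <- .layer_forward(model$layers[[i]], cur, training)
    model$layers[[i]] <- res$layer
    cur <- res$out
    if (keep_caches) caches[[i]] <- res$cache
  }
  probs <- softmax_columns(cur)
  list(model = model, logits = cur, probs = probs, caches = caches)
}

#' Column-wise softmax
#'
#' Numerically stable softmax applied to each column of a logit matrix.
#'
#' @param z Matrix `Nclass x B` (or a vector, treated as one column).
#' @return Matrix of the same shape; each column is non-negative and sums
#'   to 1.
#' @export
softmax_columns <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  zm <- sweep(z, 2L, apply(z, 2L, max), `-`)
  e <- exp(zm)
  sweep(e, 2L, colSums(e), `/`)
}

#' Backward pass
#'
#' Backpropagates the gradient of the mean cross-entropy (softmax minus
#' one-hot targets, divided by batch size) through all layers. L2
#' regularisation gradients (`2 * lambda * w` on decayed weights) are
#' added when `lambda > 0`.
#'
#' @param model A `gdnet_model`.
#' @param forward Result of [model_forward()] with `keep_caches = TRUE`.
#' @param y_onehot Target matrix `Nclass x B`.
#' @param lambda L2 regularisation constant.
#' @return List of per-layer gradient lists (same structure as params).
#' @export
model_backward <- function(model, forward, y_onehot, lambda = 0) {
  B <- ncol(y_onehot)
  dcur <- (forward$probs - y_onehot) / B
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    res <- .layer_backward(model$layers[[i]], dcur, forward$caches[[i]])
    grads[[i]] <- res$grads
    dcur <- res$dx
  }
  if (lambda > 0) {
    for (i in seq_along(model$layers)) {
      for (nm in model$layers[[i]]$meta$decay %||% character(0)) {
        grads[[i]][[nm]] <- grads[[i]][[nm]] +
          2 * lambda * model$layers[[i]]$params[[nm]]
      }
    }
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class indices for a segment batch
#'
#' @param model A trained `gdnet_model`.
#' @param x Input array `(C, Ns, B)` or a `segment_batch`.
#' @param batch_size Forward-pass chunk size.
#' @return Integer vector of 0-based predicted class indices.
#' @export
predict_classes <- function(model, x, batch_size = 256L) {
  if (inherits(x, "segment_batch")) x <- x$X
  B <- dim(x)[3]
  out <- integer(B)
  for (start in seq(1L, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B)
    fw <- model_forward(model, x[, , idx, drop = FALSE], training = FALSE)
    out[idx] <- max.col(t(fw$probs), ties.method = "first") - 1L
  }
  out
}

# ------------------------------------------------------------- parameters

#' Flatten model parameters
#'
#' @param model A `gdnet_model`.
#' @return Named list of numeric arrays, names `"L<idx>.<param>"`.
#' @export
model_params <- function(model) {
  out <- list()
  for (i in seq_along(model$layers)) {
    for (nm in names(model$layers[[i]]$params))
      out[[sprintf("L%02d.%s", i, nm)]] <- model$layers[[i]]$params[[nm]]
  }
  out
}

#' Write flattened parameters back into a model
#'
#' @param model A `gdnet_model`.
#' @param params Named list as produced by [model_params()].
#' @return The updated model.
#' @export
model_set_params <- function(model, params) {
  for (nm in names(params)) {
    i <- as.integer(sub("^L(\\d+)\\..*$", "\\1", nm))
    p <- sub("^L\\d+\\.", "", nm)
    stopifnot(length(model$layers[[i]]$params[[p]]) == length(params[[nm]]))
    model$layers[[i]]$params[[p]][] <- params[[nm]]
  }
  model
}

#' Count trainable parameters
#'
#' @param model A `gdnet_model`.
#' @return Total number of trainable parameters (convolution and attention
#'   weights, biases, batch-norm scale/shift, dense weights).
#' @export
count_parameters <- function(model) {
  sum(vapply(model_params(model), length, integer(1)))
}

#' Layer-by-layer architecture summary
#'
#' @param model A `gdnet_model`.
#' @return Data frame with layer index, type and parameter count; also
#'   serialisable to JSON via [jsonlite::toJSON()].
#' @export
model_summary <- function(model) {
  data.frame(
    layer = seq_along(model$layers),
    type = vapply(model$layers, function(l) l$type, character(1)),
    n_params = vapply(model$layers, function(l)
      sum(vapply(l$params, length, integer(1))), integer(1))
  )
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture configuration together with all
#' parameters and batch-norm buffers.
#'
#' @param model A `gdnet_model`.
#' @param path File path.
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "gdnet_model"))
  model
}

#' Shapes of the intermediate stages
#'
#' Traces a single segment through the network and records the output
#' shape after each layer, for conformance checks against the documented
#' architecture table (under ceiling semantics for the stride-2 SAME
#' convolutions, four halvings take `Ns` to roughly `Ns / 16`).
#'
#' @param model A `gdnet_model`.
#' @return Data frame with layer type and output dimensions (as a string).
#' @export
model_shapes <- function(model) {
  x <- array(0, c(model$cfg$n_channels, model$n_samples, 1L))
  cur <- x
  out <- data.frame(layer = integer(0), type = character(0),
                    shape = character(0))
  for (i in seq_along(model$layers)) {
    res <- .layer_forward(model$layers[[i]], cur, training = FALSE)
    cur <- res$out
    out <- rbind(out, data.frame(
      layer = i, type = model$layers[[i]]$type,
      shape = paste(dim(cur), collapse = "x")))
  }
  out
}

#' Extract attention gates from a trained model
#'
#' Runs a batch forward in evaluation mode and collects, for every
#' attention layer, the EEG channel-wise gate map (`C x M`, averaged over
#' the batch) and the network-wise gate vector (length `M`). The channel
#' map reads out which electrodes each feature map attends to.
#'
#' @param model A `gdnet_model` with attention enabled.
#' @param x Input array `(C, Ns, B)` or `segment_batch`.
#' @return List (one element per attention layer) of lists with `m_ec`
#'   and/or `m_sn`.
#' @export
inspect_attention <- function(model, x) {
  if (inherits(x, "segment_batch")) x <- x$X
  cur <- x
  maps <- list()
  for (i in seq_along(model$layers)) {
    res <- .layer_forward(model$layers[[i]], cur, training = FALSE)
    if (model$layers[[i]]$type == "attention") {
      entry <- list(layer = i)
      C <- model$cfg$n_channels; M <- model$cfg$n_feature_maps
      if (!is.null(res$cache$ch)) {
        G <- rowMeans(res$cache$ch$G)      # average over batch, (C*M)
        entry$m_ec <- matrix(G, C, M)
      }
      if (!is.null(res$cache$net)) entry$m_sn <- rowMeans(res$cache$net$g2)
      maps[[length(maps) + 1L]] <- entry
    }
    cur <- res$out
  }
  maps
}
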