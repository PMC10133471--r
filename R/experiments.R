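#' Frequency-recovery experiment on synthetic SSVEP data
#'
#' A scaled-down functional test of the whole stack: generate an 8-class
#' synthetic SSVEP dataset (frequencies from 8 Hz in 0.2 Hz strides,
#' 0.5 pi phase steps, 3 harmonics, SNR 0 dB, 250 Hz), split it into
#' 1-second segments, train a reduced network (8 channels, 16 feature
#' maps, 2 group blocks, attention on) on 800 training segments — of
#' which a grouped trial subset serves as the early-stopping validation
#' split — and measure accuracy on 200 held-out segments from unseen
#' trials. With `shuffle_labels = TRUE` the training labels are permuted,
#' destroying the signal-label association: accuracy should then stay at
#' chance, certifying that learning is signal-driven rather than an
#' artifact of the harness.
#'
#' @param seed Seed controlling data generation, splits, initialisation
#'   and shuffling.
#' @param shuffle_labels Permute training/validation labels (control run).
#' @param n_classes Number of stimulation frequencies.
#' @param snr_db Synthetic SNR in dB.
#' @param n_trials_per_class Trials per class (5 s each; 1 s windows give
#'   5 segments per trial).
#' @param ratio Segment window in seconds.
#' @param n_channels,n_feature_maps,n_group_blocks Reduced architecture.
#' @param max_epochs,patience Training-length controls.
#' @param verbose Print per-epoch progress.
#' @return List with `accuracy` (percent on held-out segments), `chance`
#'   (percent), `n_train`, `n_test`, `best_epoch` and the training
#'   `history`.
#' @export
frequency_recovery_experiment <- function(seed = 1L, shuffle_labels = FALSE,
                                          n_classes = 8L, snr_db = 0,
                                          n_trials_per_class = 25L,
                                          ratio = 1.0, n_channels = 8L,
                                          n_feature_maps = 16L,
                                          n_group_blocks = 2L,
                                          max_epochs = 25L, patience = 6L,
                                          verbose = FALSE) {
  table <- build_stimulus_table(n_classes = n_classes)
  syn <- synthetic_config(n_channels = n_channels, trial_duration = 5,
                          snr_db = snr_db,
                          n_trials_per_class = n_trials_per_class,
                          seed = seed)
  trials <- generate_dataset(syn, table)
  segs <- segment_dataset(trials, ratio)
  sp <- .trial_split(segs, test_fraction = 0.2, seed = seed,
                     val_fraction = 0.15)
  if (shuffle_labels) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed + 1L)
    sp$train$y <- sample(sp$train$y)
    sp$val$y <- sample(sp$val$y)
  }
  gcfg <- gdnet_config(n_channels, n_classes,
                       n_feature_maps = n_feature_maps,
                       n_group_blocks = n_group_blocks)
  tcfg <- train_config(max_epochs = max_epochs,
                       early_stop_patience = patience, seed = seed,
                       verbose = verbose)
  model <- build_model(gcfg, dim(segs$X)[2])
  model <- init_weights(model, seed = seed, sd = tcfg$init_sd)
  fit <- train_model(model, sp$train, sp$val, tcfg)
  pred <- predict_classes(fit$model, sp$test)
  list(accuracy = 100 * mean(pred == sp$test$y),
       chance = 100 / n_classes,
       n_train = length(sp$train$y) + length(sp$val$y),
       n_test = length(sp$test$y),
       best_epoch = fit$best_epoch, history = fit$history)
}
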