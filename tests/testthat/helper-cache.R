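# heavy training runs shared across test files: computed once per session
.run_cache <- new.env(parent = emptyenv())

cached_recovery <- function() {
  if (is.null(.run_cache$real))
    .run_cache$real <- frequency_recovery_experiment(seed = 1)
  .run_cache$real
}

cached_recovery_shuffled <- function() {
  if (is.null(.run_cache$shuffled))
    .run_cache$shuffled <- frequency_recovery_experiment(
      seed = 1, shuffle_labels = TRUE, max_epochs = 20, patience = 4)
  .run_cache$shuffled
}
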