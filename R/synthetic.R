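#' Configuration for the synthetic SSVEP generator
#'
#' Houses the acquisition and signal-model constants used by
#' [generate_trial()] and [generate_dataset()]. The generator emulates a
#' frequency/phase-coded SSVEP paradigm: each trial carries a harmonic
#' stack at the class frequency, scaled per channel by a topographic gain
#' profile, plus additive noise scaled to a target signal-to-noise ratio.
#'
#' @param n_channels Number of EEG channels.
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @param trial_duration Trial length in seconds (stimulation only).
#' @param n_harmonics Number of harmonics of the stimulation frequency
#'   (>= 1). Harmonic `h` enters as `harmonic_decay^(h-1) *
#'   sin(2*pi*h*f*t + h*phase)`.
#' @param harmonic_decay Per-harmonic amplitude ratio in (0, 1].
#' @param snr_db Target signal-to-noise ratio in dB: clean-signal power over
#'   noise power, averaged across channels with non-zero gain. `Inf`
#'   disables noise.
#' @param channel_gain_profile Per-channel non-negative gains (at least one
#'   positive). `NULL` selects an occipital-peaked default via
#'   [occipital_gain_profile()], under the convention that channels are
#'   ordered front-to-back so posterior (SSVEP-dominant) sites come last.
#' @param n_trials_per_class Trials generated per stimulation condition.
#' @param noise Noise model: `"white"` (Gaussian) or `"pink"` (1/f-shaped
#'   Gaussian).
#' @param seed Integer seed making the full dataset reproducible.
#'
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_channels = 8L, sampling_rate = 250,
                             trial_duration = 5, n_harmonics = 3L,
                             harmonic_decay = 0.5, snr_db = 0,
                             channel_gain_profile = NULL,
                             n_trials_per_class = 25L,
                             noise = c("white", "pink"), seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_channels >= 1, sampling_rate > 0, trial_duration > 0,
            n_harmonics >= 1, harmonic_decay > 0, harmonic_decay <= 1,
            n_trials_per_class >= 1)
  if (is.null(channel_gain_profile))
    channel_gain_profile <- occipital_gain_profile(n_channels)
  if (length(channel_gain_profile) != n_channels)
    stop("`channel_gain_profile` must have one gain per channel", call. = FALSE)
  if (any(channel_gain_profile < 0) || all(channel_gain_profile == 0))
    stop("gains must be >= 0 with at least one > 0", call. = FALSE)
  cfg <- list(
    n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
    trial_duration = trial_duration, n_harmonics = as.integer(n_harmonics),
    harmonic_decay = harmonic_decay, snr_db = snr_db,
    channel_gain_profile = as.numeric(channel_gain_profile),
    n_trials_per_class = as.integer(n_trials_per_class),
    noise = noise, seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Smooth occipital-peaked channel gain profile
#'
#' A raised-Gaussian gain bump peaked near the posterior end of the channel
#' ordering, reflecting that SSVEP power concentrates over occipital and
#' parieto-occipital electrodes. Channels are assumed ordered front-to-back.
#'
#' @param n_channels Number of channels.
#' @param floor_gain Minimum gain for anterior channels.
#' @param width Bump width as a fraction of the channel count.
#' @return Numeric vector of `n_channels` gains in `(0, 1]`.
#' @export
occipital_gain_profile <- function(n_channels, floor_gain = 0.15, width = 0.25) {
  if (n_channels == 1L) return(1)
  i <- seq_len(n_channels)
  peak <- n_channels - 0.1 * n_channels       # near the posterior end
  w <- max(width * n_channels, 1)
  floor_gain + (1 - floor_gain) * exp(-((i - peak) / w)^2)
}

#' Generate one synthetic SSVEP trial
#'
#' The clean component of channel `c` is
#' `g_c * sum_h decay^(h-1) * sin(2*pi*h*f*t + h*phase)`; noise is then
#' added and rescaled so the realized clean/noise power ratio (averaged
#' over channels with non-zero gain) matches `cfg$snr_db` exactly. Noise is
#' present on all channels, including zero-gain ones.
#'
#' @param cfg A [synthetic_config()].
#' @param table A stimulus table from [build_stimulus_table()].
#' @param class_index 0-based class index present in `table`.
#' @param seed Integer seed for this trial's noise; identical
#'   `(cfg, class_index, seed)` give bitwise-identical output.
#' @param subject_id,session_id,dataset_tag Identifier metadata.
#'
#' @return A list of class `"ssvep_trial"` with elements `data`
#'   (`n_channels x n_samples` matrix), `clean` (noise-free component),
#'   `class_index`, `frequency`, `phase`, `sampling_rate` and the
#'   identifiers.
#' @export
generate_trial <- function(cfg, table, class_index, seed = cfg$seed,
                           subject_id = "S01", session_id = "B01",
                           dataset_tag = "synthetic") {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(table, "stimulus_table"))
  row <- which(table$class_index == class_index)
  if (length(row) != 1L)
    stop("`class_index` ", class_index, " not present in the stimulus table",
         call. = FALSE)
  f   <- table$frequency[row]
  phi <- table$phase[row]
  fs  <- cfg$sampling_rate
  if (fs <= 2 * f * cfg$n_harmonics)
    stop("sampling rate too low for ", cfg$n_harmonics, " harmonics of ",
         f, " Hz (aliasing)", call. = FALSE)
  n  <- as.integer(round(cfg$trial_duration * fs))
  tt <- (seq_len(n) - 1L) / fs
  wave <- rep(0, n)
  for (h in seq_len(cfg$n_harmonics))
    wave <- wave + cfg$harmonic_decay^(h - 1) * sin(2 * pi * h * f * tt + h * phi)
  clean <- outer(cfg$channel_gain_profile, wave)   # C x n

  if (is.finite(cfg$snr_db)) {
    active <- cfg$channel_gain_profile > 0
    p_clean <- mean(rowMeans(clean[active, , drop = FALSE]^2))
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
    noise <- matrix(stats::rnorm(cfg$n_channels * n), cfg$n_channels, n)
    if (cfg$noise == "pink") noise <- .pink_shape(noise, fs)
    p_noise <- mean(rowMeans(noise[active, , drop = FALSE]^2))
    target <- p_clean / 10^(cfg$snr_db / 10)
    noise <- noise * sqrt(target / p_noise)
    data <- clean + noise
  } else {
    data <- clean
  }
  structure(list(data = data, clean = clean,
                 class_index = as.integer(class_index), frequency = f,
                 phase = phi, sampling_rate = fs, subject_id = subject_id,
                 session_id = session_id, dataset_tag = dataset_tag),
            class = "ssvep_trial")
}

# shape white Gaussian rows into 1/f ("pink") noise via FFT filtering,
# preserving unit scale on average
.pink_shape <- function(noise, fs) {
  n <- ncol(noise)
  freq <- c(0, seq_len(n - 1)) * fs / n
  freq <- pmin(freq, fs - freq)                 # two-sided
  amp <- ifelse(freq > 0, 1 / sqrt(pmax(freq, 1)), 0)
  out <- t(apply(noise, 1L, function(x) Re(stats::fft(stats::fft(x) * amp,
                                                      inverse = TRUE)) / n))
  out / sqrt(mean(out^2))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a class-balanced synthetic SSVEP dataset
#'
#' Produces exactly `cfg$n_trials_per_class` trials for every class in
#' `table`, reproducibly from `cfg$seed`: per-trial noise seeds are drawn
#' once from `cfg$seed`, so the full dataset is a pure function of
#' `(cfg, table)`.
#'
#' @param cfg A [synthetic_config()].
#' @param table A [build_stimulus_table()] table.
#' @return A list of `ssvep_trial` objects of class `"ssvep_dataset"`, with
#'   the generating `cfg` and `table` attached as attributes.
#' @export
generate_dataset <- function(cfg, table) {
  stopifnot(inherits(cfg, "synthetic_config"))
  classes <- table$class_index
  n_total <- length(classes) * cfg$n_trials_per_class
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(cfg$seed)
  trial_seeds <- sample.int(.Machine$integer.max, n_total)
  trials <- vector("list", n_total)
  i <- 0L
  for (k in classes) {
    for (r in seq_len(cfg$n_trials_per_class)) {
      i <- i + 1L
      trials[[i]] <- generate_trial(cfg, table, k, seed = trial_seeds[i],
                                    subject_id = "S01",
                                    session_id = sprintf("B%02d", r))
    }
  }
  structure(trials, class = "ssvep_dataset", config = cfg, table = table)
}

#' Realized signal-to-noise ratio of a synthetic trial
#'
#' Recomputes the clean/noise power ratio of a generated trial from its
#' stored clean component, averaged over channels with non-zero gain.
#'
#' @param trial An `ssvep_trial` carrying its `clean` component.
#' @param gains The channel gain profile used at generation.
#' @return SNR in dB (`Inf` for noiseless trials).
#' @export
realized_snr_db <- function(trial, gains) {
  stopifnot(inherits(trial, "ssvep_trial"), !is.null(trial$clean))
  active <- gains > 0
  noise <- trial$data - trial$clean
  p_noise <- mean(rowMeans(noise[active, , drop = FALSE]^2))
  if (p_noise == 0) return(Inf)
  p_clean <- mean(rowMeans(trial$clean[active, , drop = FALSE]^2))
  10 * log10(p_clean / p_noise)
}
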