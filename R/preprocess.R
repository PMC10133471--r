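#' Band-pass filter specification
#'
#' Chebyshev Type I band-pass specification used for raw EEG trials:
#' passband 6--90 Hz with stopband corners at 4 and 100 Hz. The filter
#' order is not fixed here; [design_bandpass()] chooses the minimal
#' Chebyshev Type I order meeting the ripple and attenuation bounds at the
#' stated corners.
#'
#' @param passband Length-2 passband corner frequencies in Hz.
#' @param stopband Length-2 stopband corner frequencies in Hz.
#' @param passband_ripple Maximum passband ripple in dB.
#' @param stopband_attenuation Minimum stopband attenuation in dB.
#' @param zero_phase Apply forward-backward (zero-phase) by default in
#'   [filter_trial()]. Zero-phase application squares the magnitude
#'   response, doubling both ripple and attenuation in dB.
#' @return A list of class `"filter_spec"`.
#' @export
filter_spec <- function(passband = c(6, 90), stopband = c(4, 100),
                        passband_ripple = 1, stopband_attenuation = 40,
                        zero_phase = TRUE) {
  stopifnot(length(passband) == 2, length(stopband) == 2,
            stopband[1] < passband[1], passband[1] < passband[2],
            passband[2] < stopband[2],
            passband_ripple > 0, stopband_attenuation > 0)
  structure(list(passband = passband, stopband = stopband,
                 passband_ripple = passband_ripple,
                 stopband_attenuation = stopband_attenuation,
                 zero_phase = zero_phase),
            class = "filter_spec")
}

#' Design the Chebyshev Type I band-pass filter
#'
#' Uses `signal::cheb1ord()` to find the minimal filter order meeting the
#' specification and `signal::cheby1()` to compute the coefficients. The
#' design is validated: coefficients must be finite and all poles strictly
#' inside the unit circle.
#'
#' @param spec A [filter_spec()].
#' @param sampling_rate Sampling rate in Hz; the Nyquist frequency must lie
#'   above the upper stopband corner.
#' @return A list of class `"bandpass_filter"` with elements `b`, `a`
#'   (transfer-function coefficients), `order`, `spec`, `sampling_rate`.
#' @export
design_bandpass <- function(spec = filter_spec(), sampling_rate = 250) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- sampling_rate / 2
  if (spec$stopband[2] >= nyq)
    stop("sampling rate ", sampling_rate,
         " Hz too low: upper stopband corner ", spec$stopband[2],
         " Hz is at or above Nyquist", call. = FALSE)
  ord <- signal::cheb1ord(Wp = spec$passband / nyq, Ws = spec$stopband / nyq,
                          Rp = spec$passband_ripple,
                          Rs = spec$stopband_attenuation)
  fl <- signal::cheby1(ord)
  if (!all(is.finite(fl$b)) || !all(is.finite(fl$a)))
    stop("filter design produced non-finite coefficients", call. = FALSE)
  poles <- polyroot(rev(fl$a))
  if (any(Mod(poles) >= 1))
    stop("designed filter is unstable (pole on/outside unit circle)",
         call. = FALSE)
  structure(list(b = fl$b, a = fl$a, order = ord$n, spec = spec,
                 sampling_rate = sampling_rate),
            class = "bandpass_filter")
}

#' Magnitude response of a designed filter
#'
#' @param filt A [design_bandpass()] result.
#' @param freqs Frequencies in Hz at which to evaluate.
#' @param zero_phase Report the squared (forward-backward) magnitude.
#' @return Magnitude response in dB at `freqs`.
#' @export
filter_response_db <- function(filt, freqs, zero_phase = FALSE) {
  stopifnot(inherits(filt, "bandpass_filter"))
  w <- 2 * pi * freqs / filt$sampling_rate
  z <- exp(-1i * w)
  h <- sapply(z, function(zi)
    sum(filt$b * zi^(seq_along(filt$b) - 1)) /
      sum(filt$a * zi^(seq_along(filt$a) - 1)))
  db <- 20 * log10(Mod(h))
  if (zero_phase) db <- 2 * db
  db
}

#' Band-pass filter one trial
#'
#' Filters each EEG channel independently. By default the filter is applied
#' forward and backward (`signal::filtfilt`), giving zero phase distortion
#' at the cost of squaring the magnitude response.
#'
#' @param trial An `ssvep_trial`.
#' @param spec A [filter_spec()], or a pre-designed [design_bandpass()]
#'   object (avoids repeating the design per trial).
#' @return The trial with filtered `data` (shape preserved; `clean` is
#'   dropped since it no longer matches the filtered signal).
#' @export
filter_trial <- function(trial, spec = filter_spec()) {
  stopifnot(inherits(trial, "ssvep_trial"))
  if (!all(is.finite(trial$data)))
    stop("trial contains NaN/Inf samples", call. = FALSE)
  filt <- if (inherits(spec, "bandpass_filter")) spec
          else design_bandpass(spec, trial$sampling_rate)
  if (abs(filt$sampling_rate - trial$sampling_rate) > 1e-9)
    stop("filter designed for ", filt$sampling_rate,
         " Hz but trial sampled at ", trial$sampling_rate, " Hz",
         call. = FALSE)
  zp <- filt$spec$zero_phase
  flt <- signal::Arma(b = filt$b, a = filt$a)
  out <- trial$data
  for (c in seq_len(nrow(out))) {
    out[c, ] <- if (zp) signal::filtfilt(flt, trial$data[c, ])
                else as.numeric(signal::filter(flt, trial$data[c, ]))
  }
  trial$data <- out
  trial$clean <- NULL
  trial
}

#' Crop a trial to its stimulation interval
#'
#' Removes the leading visual-cue interval and the trailing offset interval
#' from a trial, keeping only the flicker-stimulation record. In the
#' public 40-target paradigm a 6 s trial comprises 0.5 s of gaze shifting,
#' 5 s of stimulation and a 0.5 s offset.
#'
#' @param trial An `ssvep_trial`.
#' @param cue_s Leading cue duration to drop, in seconds.
#' @param offset_s Trailing offset duration to drop, in seconds.
#' @return The cropped trial.
#' @export
crop_stimulation <- function(trial, cue_s = 0.5, offset_s = 0.5) {
  stopifnot(inherits(trial, "ssvep_trial"), cue_s >= 0, offset_s >= 0)
  fs <- trial$sampling_rate
  n <- ncol(trial$data)
  lead <- as.integer(round(cue_s * fs))
  tail_ <- as.integer(round(offset_s * fs))
  keep <- n - lead - tail_
  if (keep <= 0)
    stop("cropping ", cue_s, " + ", offset_s,
         " s leaves no stimulation samples in a ", n / fs, " s trial",
         call. = FALSE)
  idx <- (lead + 1L):(n - tail_)
  trial$data <- trial$data[, idx, drop = FALSE]
  if (!is.null(trial$clean)) trial$clean <- trial$clean[, idx, drop = FALSE]
  trial
}

#' Split a trial into fixed-length labelled segments
#'
#' Cuts the trial into consecutive non-overlapping windows of
#' `ratio` seconds (`ratio * sampling_rate` samples); the trailing
#' remainder shorter than one window is discarded. Every segment inherits
#' the trial's class label.
#'
#' @param trial An `ssvep_trial`.
#' @param ratio Window length in seconds (e.g. 0.2, 0.4, ..., 1.0).
#' @return A `segment_batch`: list with `X` (array
#'   `n_channels x n_samples x n_segments`), `y` (0-based class indices),
#'   `ratio`, `sampling_rate`, `source_trial_ids`.
#' @export
segment_trial <- function(trial, ratio) {
  stopifnot(inherits(trial, "ssvep_trial"), ratio > 0)
  fs <- trial$sampling_rate
  win <- as.integer(round(ratio * fs))
  if (win < 1L) stop("window shorter than one sample", call. = FALSE)
  len <- ncol(trial$data)
  t_seg <- len %/% win
  C <- nrow(trial$data)
  X <- array(0, c(C, win, t_seg))
  if (t_seg > 0L)
    for (s in seq_len(t_seg))
      X[, , s] <- trial$data[, ((s - 1L) * win + 1L):(s * win)]
  tid <- paste(trial$dataset_tag, trial$subject_id, trial$session_id,
               trial$class_index, sep = "/")
  structure(list(X = X, y = rep(trial$class_index, t_seg), ratio = ratio,
                 sampling_rate = fs,
                 source_trial_ids = rep(tid, t_seg)),
            class = "segment_batch")
}

#' Segment a whole dataset
#'
#' Applies [segment_trial()] to every trial and concatenates the results
#' into one labelled segment batch.
#'
#' @param trials An `ssvep_dataset` (or plain list of trials).
#' @param ratio Window length in seconds.
#' @return A `segment_batch` covering all trials.
#' @export
segment_dataset <- function(trials, ratio) {
  batches <- lapply(seq_along(trials), function(i) {
    b <- segment_trial(trials[[i]], ratio)
    # disambiguate repeated (subject, session, class) ids across the list
    b$source_trial_ids <- paste0(b$source_trial_ids, "#", i)
    b
  })
  bind_segment_batches(batches)
}

#' Concatenate segment batches
#'
#' @param batches List of `segment_batch` objects with identical channel
#'   count, window length and sampling rate.
#' @return A single `segment_batch`.
#' @export
bind_segment_batches <- function(batches) {
  batches <- Filter(function(b) length(b$y) > 0, batches)
  stopifnot(length(batches) > 0)
  C <- dim(batches[[1]]$X)[1]; win <- dim(batches[[1]]$X)[2]
  n <- sum(vapply(batches, function(b) length(b$y), integer(1)))
  X <- array(0, c(C, win, n)); y <- integer(n); ids <- character(n)
  at <- 0L
  for (b in batches) {
    stopifnot(dim(b$X)[1] == C, dim(b$X)[2] == win)
    k <- length(b$y)
    X[, , (at + 1L):(at + k)] <- b$X
    y[(at + 1L):(at + k)] <- b$y
    ids[(at + 1L):(at + k)] <- b$source_trial_ids
    at <- at + k
  }
  structure(list(X = X, y = y, ratio = batches[[1]]$ratio,
                 sampling_rate = batches[[1]]$sampling_rate,
                 source_trial_ids = ids),
            class = "segment_batch")
}

#' Subset a segment batch
#'
#' @param batch A `segment_batch`.
#' @param idx Segment indices to keep.
#' @return The subset `segment_batch`.
#' @export
subset_segments <- function(batch, idx) {
  structure(list(X = batch$X[, , idx, drop = FALSE], y = batch$y[idx],
                 ratio = batch$ratio, sampling_rate = batch$sampling_rate,
                 source_trial_ids = batch$source_trial_ids[idx]),
            class = "segment_batch")
}
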