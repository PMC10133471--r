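filt250 <- design_bandpass(filter_spec(), 250)
tab8 <- build_stimulus_table(n_classes = 8)

make_tone_trial <- function(freqs, amps, fs = 250, dur = 4) {
  n <- fs * dur
  tt <- (seq_len(n) - 1) / fs
  x <- rowSums(sapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * tt)))
  structure(list(data = matrix(x, 1), clean = NULL, class_index = 0L,
                 frequency = freqs[1], phase = 0, sampling_rate = fs,
                 subject_id = "S", session_id = "B", dataset_tag = "tone"),
            class = "ssvep_trial")
}

test_that("the designed filter meets the passband/stopband corners", {
  expect_true(all(is.finite(filt250$b)), all(is.finite(filt250$a)))
  expect_true(all(Mod(polyroot(rev(filt250$a))) < 1))       # stable
  # inside the passband (away from transition edges) within ripple of 0 dB
  pb <- filter_response_db(filt250, c(10, 20, 48, 70, 85))
  expect_true(all(pb <= 0.01 & pb >= -filt250$spec$passband_ripple - 0.01))
  # outside the stopband corners: >= 40 dB down
  sb <- filter_response_db(filt250, c(2, 3.5, 102, 110))
  expect_true(all(sb <= -40))
})

test_that("sampling rates with Nyquist below the stopband corner error", {
  expect_error(design_bandpass(filter_spec(), 150), "Nyquist")
})

test_that("tones are passed or attenuated according to the band", {
  # zero-phase (forward-backward) application squares the magnitude
  # response: passband gain lies within twice the 1 dB design ripple
  tr <- make_tone_trial(c(50), c(1))
  out <- filter_trial(tr, filt250)
  mid <- 300:700    # avoid filtfilt edge transients
  gain <- sqrt(mean(out$data[1, mid]^2)) / sqrt(mean(tr$data[1, mid]^2))
  expect_gt(20 * log10(gain), -2.1)
  expect_lt(20 * log10(gain), 0.1)
  tr2 <- make_tone_trial(c(2), c(1))
  out2 <- filter_trial(tr2, filt250)
  # zero-phase application doubles the single-pass 40 dB attenuation
  expect_lt(sqrt(mean(out2$data[1, mid]^2)),
            0.01 * sqrt(mean(tr2$data[1, mid]^2)))
})

test_that("a 10 Hz + 2 Hz mixture reduces to the 10 Hz tone", {
  mix <- make_tone_trial(c(10, 2), c(1, 1))
  pure <- make_tone_trial(c(10), c(1))
  out <- filter_trial(mix, filt250)
  mid <- 300:700
  # the 2 Hz component is gone: what remains is proportional to the
  # 10 Hz tone (within the squared passband ripple) and in phase with it
  expect_gt(stats::cor(out$data[1, mid], pure$data[1, mid]), 0.9999)
  gain <- sqrt(mean(out$data[1, mid]^2)) / sqrt(mean(pure$data[1, mid]^2))
  expect_gt(20 * log10(gain), -2.1)
  expect_lt(20 * log10(gain), 0.1)
})

test_that("filtering is linear: zeros map to zeros, channels independent", {
  z <- make_tone_trial(c(10), c(0))
  expect_equal(filter_trial(z, filt250)$data, z$data)
  # two channels filtered jointly equal each filtered alone (permutation
  # commutes with filtering)
  t1 <- make_tone_trial(c(10), c(1)); t2 <- make_tone_trial(c(30), c(1))
  both <- t1; both$data <- rbind(t1$data, t2$data)
  out <- filter_trial(both, filt250)
  expect_equal(out$data[1, ], filter_trial(t1, filt250)$data[1, ])
  expect_equal(out$data[2, ], filter_trial(t2, filt250)$data[1, ])
})

test_that("zero-phase filtering introduces no group delay", {
  tr <- make_tone_trial(c(20), c(1))
  out <- filter_trial(tr, filt250)
  mid <- 300:700
  cc <- stats::ccf(out$data[1, mid], tr$data[1, mid], lag.max = 5,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filtering twice matches the squared response on a tone", {
  tr <- make_tone_trial(c(7), c(1))      # transition region: partial gain
  once <- filter_trial(tr, filt250)
  twice <- filter_trial(once, filt250)
  mid <- 400:600
  g1 <- sqrt(mean(once$data[1, mid]^2)) / sqrt(mean(tr$data[1, mid]^2))
  g2 <- sqrt(mean(twice$data[1, mid]^2)) / sqrt(mean(tr$data[1, mid]^2))
  expect_equal(g2, g1^2, tolerance = 0.05)
})

test_that("non-finite samples are rejected", {
  tr <- make_tone_trial(c(10), c(1))
  tr$data[1, 5] <- NaN
  expect_error(filter_trial(tr, filt250), "NaN")
})

test_that("cropping removes cue and offset intervals", {
  cfg <- synthetic_config(n_channels = 2, trial_duration = 6, snr_db = Inf)
  tr <- generate_trial(cfg, tab8, 0L)
  out <- crop_stimulation(tr, 0.5, 0.5)
  expect_equal(ncol(out$data), 5 * 250)
  expect_equal(out$data, tr$data[, 126:1375])
  expect_equal(crop_stimulation(tr, 0, 0)$data, tr$data)
  short <- tr; short$data <- tr$data[, 1:225, drop = FALSE]
  expect_error(crop_stimulation(short, 0.5, 0.5), "no stimulation samples")
})

test_that("segmentation yields floor(Len / window) segments and keeps labels", {
  cfg <- synthetic_config(n_channels = 2, trial_duration = 5, snr_db = 0)
  tr <- generate_trial(cfg, tab8, 5L, seed = 3)     # 1250 samples
  s02 <- segment_trial(tr, 0.2)
  expect_equal(dim(s02$X), c(2, 50, 25))
  expect_true(all(s02$y == 5L))
  s10 <- segment_trial(tr, 1.0)
  expect_equal(dim(s10$X), c(2, 250, 5))
  # exactly one window: identity content
  one <- tr; one$data <- tr$data[, 1:50, drop = FALSE]
  s1 <- segment_trial(one, 0.2)
  expect_equal(dim(s1$X)[3], 1)
  expect_equal(s1$X[, , 1], one$data)
  # window longer than trial: empty batch, not an error
  s0 <- segment_trial(one, 1.0)
  expect_equal(dim(s0$X)[3], 0)
  expect_length(s0$y, 0)
})

test_that("reassembling segments reproduces a prefix of the trial", {
  cfg <- synthetic_config(n_channels = 3, trial_duration = 1.3, snr_db = 0)
  tr <- generate_trial(cfg, tab8, 1L, seed = 8)
  s <- segment_trial(tr, 0.4)
  t_seg <- dim(s$X)[3]
  expect_equal(t_seg, 3)       # floor(325 / 100)
  rebuilt <- do.call(cbind, lapply(seq_len(t_seg), function(i) s$X[, , i]))
  expect_equal(rebuilt, tr$data[, seq_len(100 * t_seg)])
})

test_that("segment class histogram is the trial histogram scaled by t", {
  tab2 <- build_stimulus_table(n_classes = 2)
  cfg <- synthetic_config(n_channels = 2, trial_duration = 2,
                          n_trials_per_class = 3, snr_db = 0)
  ds <- generate_dataset(cfg, tab2)
  segs <- segment_dataset(ds, 0.5)
  expect_equal(unname(table(segs$y)), c(12L, 12L), ignore_attr = TRUE)
  expect_length(unique(segs$source_trial_ids), 6)
})
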