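---
title: "Group depth-wise convolution and EEG attention for SSVEP frequency recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group depth-wise convolution and EEG attention for SSVEP frequency recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A steady-state visually evoked potential (SSVEP) is the periodic cortical
response elicited when a subject attends a flickering stimulus: the EEG
over occipital cortex oscillates at the flicker frequency and its
harmonics. In a 40-target speller paradigm, targets flicker at 8--15.8 Hz
in 0.2 Hz strides with a 0.5&pi; phase increment between adjacent
frequencies, and decoding reduces to a 40-class classification problem on
short multi-channel EEG segments. `gdneteeg` implements a convolutional
classifier built around two ideas:

1. **Group depth-wise convolution.** Standard EEG convolutional networks
   apply the *same* 1D temporal kernel to every electrode, so every row of
   a feature map carries the same spectral content. Brain regions differ
   in their harmonic content, however, so here each EEG channel row gets
   its *own* learned kernel per (input map, output map) pair. For output
   map $i$, channel $c$ in block $l$:
   $$Y_i^{c,l} = f\!\Big(B_i^{c,l} + \sum_{j=1}^{m^{l-1}} K_{i,j}^{c,l} \ast Y_j^{c,l-1}\Big),$$
   with $f$ a LeakyReLU, kernels of length 17 and temporal stride 2 under
   SAME padding. The channel dimension is never mixed inside these
   blocks, so different electrodes can specialise in different frequency
   combinations.

2. **EEG attention.** After each group block a two-stage multiplicative
   gate refines the feature cube $F \in \mathbb{R}^{C \times M \times L}$.
   The *channel-wise* stage pools each map along its feature length with
   both average and max pooling, mixes the two pooled descriptors with one
   learned affine combination per map, and squashes with a sigmoid,
   giving $M_{EC} \in (0,1)^{C \times M}$; $F' = M_{EC} \odot F$
   highlights the electrodes ("essential nodes") each map relies on. The
   *network-wise* stage pools $F'$ globally per map, passes both pooled
   vectors through a shared one-hidden-layer MLP ($W_0$, $W_1$, rectifier
   between, no biases), sums element-wise and squashes:
   $M_{SN} = \sigma(W_1 W_0 F^{SN}_{avg} + W_1 W_0 F^{SN}_{max})$;
   $F'' = M_{SN} \odot F'$ weights whole maps interpreted as specialised
   brain networks. Because both gates lie strictly inside $(0,1)$, the
   module is shape-preserving and element-wise contractive, and with all
   gate parameters at zero it scales the cube by exactly
   $0.5 \times 0.5 = 0.25$ — properties the test suite checks directly.

The full stack is: temporal convolution (64 maps, $1\times17$, stride 1,
batch norm) &rarr; four group blocks (each followed by attention when
enabled) &rarr; dropout 0.5 &rarr; depth-wise separable head (a $C\times1$
spatial collapse with ELU, then a $1\times1$ point-wise mix down to 16
maps with batch norm, ELU, dropout 0.5) &rarr; a single dense layer with
identity activation and softmax. No pooling layers are used anywhere;
temporal resolution is reduced only by the stride-2 convolutions.

## Tunable parameters

| parameter | default | unit | notes |
|---|---|---|---|
| `n_feature_maps` (K) | 64 | maps | reduced to 16 in the desk-scale experiments |
| `kernel_length` | 17 | samples | 68 ms at 250 Hz |
| `n_group_blocks` | 4 | blocks | stride 2 each: `Ns` &rarr; ~`Ns`/16 |
| `dropout_rate` | 0.5 | — | after the block stack and after the point-wise layer only |
| `pointwise_maps` | 16 | maps | parameter reduction in the head |
| `attention_reduction` (r) | 8 | — | MLP hidden width `max(1, K/r)` |
| `leaky_slope` | 0.01 | — | LeakyReLU negative slope |
| `learning_rate` | 0.001 | — | Adam |
| `batch_size` | 64 | segments | a trial-batching mode (`batch_unit = "trials"`) is available |
| `l2_lambda` | 0.001 | — | loss is `CE + lambda * sum(w^2)` over multiplicative weights |
| `init_sd` | 0.1 | — | Gaussian init, mean 0, variance 0.01 |
| `early_stop_patience` | 10 | epochs | on validation loss; best weights restored |

## The synthetic generator

Because the public 40-target recordings cannot be redistributed with a
package, all tests run on synthetic trials from `generate_trial()`. The
clean component of channel $c$ is
$$s_c(t) = g_c \sum_{h=1}^{H} d^{\,h-1} \sin(2\pi h f t + h\varphi),$$
with $f, \varphi$ from the stimulus table, $H = 3$ harmonics, decay
$d = 0.5$, and a smooth occipital-peaked gain profile $g_c$ (channels are
ordered front-to-back, so posterior channels get the largest gains —
matching where SSVEP power actually concentrates). White Gaussian noise
(optionally 1/f-shaped) is added on **all** channels and rescaled so the
realized clean/noise power ratio over non-zero-gain channels equals
`snr_db` exactly. The default SNR of 0 dB was chosen once as a
plausible-but-noisy regime for raw EEG narrowband responses.

What the generator deliberately does **not** emulate: eye-blink/EMG
artifacts, non-stationarity across a session, realistic inter-channel
noise covariance (noise is independent across electrodes), inter-subject
variability, or volume-conduction forward physics. Consequently a passing
frequency-recovery test certifies that the architecture, gradients and
training loop can extract frequency/phase-coded periodic structure from
noisy multichannel data — it does not certify real-data accuracy levels,
which depend on all of the omitted factors.

## Preprocessing

Raw trials are band-passed with a Chebyshev Type I filter, passband
6--90 Hz, stopband corners 4/100 Hz. The corner specification determines
the minimal order automatically (`signal::cheb1ord`; order 7, i.e. a
14-pole band-pass) for 1 dB passband ripple and 40 dB stopband
attenuation; the design is validated for stability (all poles inside the
unit circle). Filtering is applied forward-backward by default
(`signal::filtfilt`), which removes group delay at the cost of squaring
the magnitude response (2 dB worst-case passband droop, 80 dB stopband) —
delay-free segment boundaries were judged more important than the extra
ripple. Trials from cue-based paradigms are cropped
(`crop_stimulation()`, 0.5 s cue + 0.5 s offset by default); synthetic
trials are generated stimulation-only and need no cropping. Segmentation
is strictly non-overlapping with the trailing remainder discarded, so a
5 s trial yields 25/5 segments at 0.2/1.0 s windows.

## Numerical choices

* **SAME + stride 2 length semantics.** Output length is
  $\lceil L/2 \rceil$; four halvings take 250 &rarr; 125 &rarr; 63 &rarr;
  32 &rarr; 16, which is how the nominal "`Ns`/16" is realised (and 50
  &rarr; 4 rather than 3.125).
* **Bias placement.** Convolutions immediately followed by batch norm
  (temporal, point-wise) carry no bias (it would be absorbed); the group
  blocks keep their per-(map, channel) bias because the activation is
  applied *before* their batch norm, and the spatial collapse keeps a
  per-map bias.
* **Batch norm.** Per-feature-map statistics over all other axes,
  population variance in-batch, running statistics with momentum 0.1 and
  eps 1e-5 for evaluation mode.
* **Loss.** Mean categorical cross-entropy per segment plus
  $\lambda \sum w^2$ over multiplicative weights only (kernels, attention
  mixing/MLP weights, dense matrix); biases and batch-norm scale/shift
  are neither decayed nor counted. A predicted probability of exactly 0
  at the true class is clamped at 1e-12 with a message rather than
  producing `-Inf`.
* **Max-pool ties** are broken by taking the first maximiser; only the
  pooled value enters the forward pass, and gradient routing to a single
  maximiser is the standard subgradient choice.
* **Determinism.** All randomness (weight init, shuffling, dropout,
  noise) flows through R's RNG from explicit seeds; per-trial noise seeds
  are pre-drawn so a dataset is a pure function of its configuration.
  Repeated single-threaded runs produce identical metric files.

The forward and backward passes are implemented in R over BLAS matrix
products, with the grouped im2col gather/scatter in compiled code. Every
convolutional and attention operation is tested against an independent
nested-loop oracle, and the full backward pass against central-difference
numerical gradients (worst relative error observed ~1e-6).

## Design choices where the design was open

* **Activation in group blocks**: the block applies LeakyReLU to the
  convolution (plus bias) and batch-normalises afterwards; a documented
  switch to a purely linear block is `leaky_slope = 1` in spirit, but the
  nonlinear reading was preferred because the defining equation names the
  activation explicitly.
* **Attention placement**: one (independently parameterised) attention
  module after *each* group block. Sharing parameters across blocks is a
  config choice away (`build_model` assembles per-block layers), but
  independent parameters are the standard for stacked attention.
* **Channel-attention realisation**: the "M 1&times;1 filters over the
  stacked (avg, max) pooled maps" is realised as one affine combination
  of the descriptor pair per map, shared across electrodes within that
  map — the fewest-parameter reading consistent with per-map filters.
* **MLP details**: reduction ratio r = 8, rectifier hidden nonlinearity,
  no MLP biases (only $W_0$, $W_1$ are specified).
* **Base phase** of class 0 is 0; only the 0.5&pi; increment between
  adjacent classes is fixed by the paradigm.
* **Fold construction**: k-fold splits are stratified by class and
  grouped by trial, so segments of one trial never straddle train/test —
  segment-level splitting would leak within-trial autocorrelation and
  overstate accuracy.
* **Batch counting**: `batch_size` counts segments by default; the
  trial-batching mode (`t x D_b` segments per step) matches the loss
  normalisation written over trials exactly.
* **32-channel montage**: no canonical 32-electrode list exists for
  "occipital, parietal, centro-parietal, central" coverage; the shipped
  `cp32` list (all O/PO/P/CP labels plus six central electrodes) is this
  package's documented reading, as is the canonical front-to-back
  64-channel ordering used for synthetic data.
* **CBAM ablation** (`model6`): reduction ratio 8 and a 7-tap spatial
  kernel, the defaults of the published block.

## Problem sizes used in the shipped experiments

The frequency-recovery experiment trains the reduced network (8 channels,
16 maps, 2 group blocks, attention on) on an 8-class synthetic set —
25 five-second trials per class at 0 dB SNR, split by whole trials into
800 training segments (of which ~120 serve as the early-stopping
validation split) and 200 held-out test segments of 1 s each — for up to
25 epochs. The ablation comparison (full vs. shallow vs. no-attention)
uses 8 classes at −8 dB SNR, 10 two-second trials per class, 0.5 s
windows and 10 epochs over five seeds. These sizes are the package's
choice of a desk-scale experiment: large enough that chance-level
performance is rejected overwhelmingly, small enough to re-run routinely.

## Known limitations

* Training is CPU-bound and single-threaded beyond BLAS; the
  implementation is meant for method study and desk-scale experiments,
  not for reproducing GPU-scale accuracy tables on the public datasets.
* The MAT reader requires the optional R.matlab package; without it, use
  `trials_from_array()` on data imported by other means.
* Accuracy numbers obtained on synthetic data do not transfer to real
  recordings (see the generator's non-goals above).
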