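---
title: "Methods: sEMG silent speech recognition with a parallel inception CNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sEMG silent speech recognition with a parallel inception CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, assumptions and numerical choices
behind `semgssr`. It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` themselves compute.

## The recognition problem

A silent speech interface decodes intended utterances from muscle
activity rather than sound. The setting served by this package is a
fixed phrase vocabulary: six bipolar sEMG channels over speech-related
facial and neck muscles, sampled at 1,000 Hz, one 2 s epoch (2,000
samples per channel) per uttered phrase, 101 classes (100 phrases plus a
non-content baseline, class 0), with every phrase produced once per
session and sessions repeated per subject. The classifier's task is
101-way (or, on reduced problems, k-way) epoch classification.

## Synthetic data generator

No public corpus with this structure exists, so the package generates
one. The generative model per epoch and channel is

    x(t) = g_ch * e_ch(t) * c(t) + d_ch + A * sin(2*pi*50*t + phi) + w(t)

* `e_ch(t)` — the class's activation envelope: a sum of 1–3 Gaussian
  bursts per channel (center, width, amplitude), drawn deterministically
  from the class index and the master seed. This mimics phasic muscle
  activation without claiming physiological realism (no motor-unit
  model, no articulatory content).
* `c(t)` — the sEMG carrier: white Gaussian noise band-passed to
  20–450 Hz, so the "signal" band sits inside the 10–400 Hz analysis
  band and survives preprocessing.
* `g_ch`, `d_ch` — per-subject channel gains (log-normal around 1,
  sd 0.25 on the log scale) and DC offsets (uniform on ±0.5 by
  default), standing in for electrode placement and physiology
  differences among users; a `gain_shift` multiplier manufactures
  strong domain shift for transfer experiments.
* `A sin(2π·50t + φ)` — powerline interference, amplitude 0.5 by
  default, with a fresh phase per epoch so the notch filter cannot rely
  on phase.
* `w(t)` — white sensor noise, sd 0.2 by default.

Amplitudes are arbitrary units; the acquisition hardware this emulates
publishes no calibration, so only ratios (separation vs. noise) matter.
Defaults were chosen once as a plausible mid-SNR regime: burst
amplitudes of order 1 against carrier-and-noise fluctuations of order
0.2.

**Separation control.** Every burst amplitude scales linearly with the
`separation` parameter. Consequently the mean pairwise L2 distance
between class envelopes is strictly increasing in `separation`, and at
`separation = 0` *all* classes — including the baseline — collapse to
artifact-plus-noise, so any classifier is provably at chance. This is
the degenerate end of the dial; the property-based tests exploit both
ends.

**Seed discipline.** One master seed; per-class template seeds and
per-epoch seeds are derived by a stable integer hash of
(subject, session, class), so any sub-block of the corpus can be
regenerated independently and the whole dataset is byte-reproducible.
The generator saves and restores the caller's RNG state.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real recordings: motor-unit discharge statistics,
inter-session electrode drift, movement artifacts, cross-talk between
channels, class-dependent utterance duration, or the acoustic/semantic
structure of any language. Results on synthetic data demonstrate that
the pipeline is implemented correctly and can exploit the statistical
structure it assumes, not that a particular accuracy is attainable on
human data.

## Preprocessing

The cleaning chain mirrors standard sEMG practice: a Butterworth-style
notch at the 50 Hz mains frequency, then a 10–400 Hz band-pass covering
the effective sEMG band.

* The notch is a 2nd-order IIR biquad (audio-EQ cookbook form) with
  quality factor 30 (≈1.7 Hz bandwidth). The band-pass is a 4th-order
  Butterworth. Orders are not dictated by the protocol; these are the
  common defaults and meet the attenuation targets the tests assert
  (≥ 20 dB at 50 Hz, ≤ 5% deviation at 100/200 Hz) by analytic
  frequency response.
* Both filters run zero-phase (forward–backward). The pipeline is
  offline, and zero group delay keeps burst timing aligned with the
  sliding windows; the effective magnitude response is the squared
  single-pass response, which the analytic `filter_response()` reports.
* Millisecond-to-sample conversion is `round(ms * fs / 1000)`, exact at
  1 kHz. Sliding windows start at the 250 ms trim and advance by the
  hop; incomplete trailing windows are discarded, giving
  `1 + floor((N - trim - W) / hop)` windows — exactly 32 on the
  protocol's 2,000-sample channels.

## Feature extraction

Per 200-sample window: MAV, population VAR, RMS and MWL as defined in
the README. Two conventions worth noting: VAR and the RMS identity
`RMS² = VAR + mean²` use the population normalization (divide by W);
MWL sums the W−1 absolute first differences but divides by W.

MNF (spectral centroid) and MDF (median frequency) come from a
single-window periodogram with a Hann taper — the windows are too short
for Welch averaging to have positive degrees of freedom left. The
periodogram is renormalized so its total equals the window's population
variance exactly, making the discrete Parseval identity an invariant
rather than an approximation; this rescaling is per-window and cancels
in both MNF and MDF. MDF takes the smallest grid frequency whose
cumulative power reaches half the total (deterministic tie-break,
faithful to the defining balance up to discretization). Zero-power
windows make both undefined: bare calls raise an error, while batch
TFD6 extraction substitutes 0 and warns, keeping batch jobs total.

Spectral features operate on the trimmed 1,750-sample signal with
centered, reflect-padded framing (FFT window 200, hop 50), which yields
`1 + floor(1750/50) = 36` frames — the only framing convention
consistent with the protocol's three printed numbers (window 200, hop
50, 36 frames). Mel filtering uses the HTK Mel scale
(`2595·log10(1 + f/700)`), 36 unit-height triangular filters spanning
0 to fs/2, applied to the *power* spectrogram (the common convention in
Mel-feature references), then `log(. + 1e-10)`; the additive floor
makes silent input well-defined (`log(1e-10)` everywhere). The STFT
feature itself is emitted as magnitude, a reasonable default where the
convention is unstated. MFCC uses 12 Mel filters, an orthonormal
DCT-II keeping all 12 coefficients, and first/second-order deltas by
the standard centered two-frame regression with edge replication,
stacked `[cepstra | Δ | ΔΔ]` to a 36 × 36 matrix per channel. Spectral
features are computed after preprocessing; whether to compute them on
raw or cleaned signals is an open convention, and cleaning first keeps
all nine methods on identical input.

## Model architectures

**PICNN.** One inception module per channel with *independent* weights
(no sharing): the point of the parallel design is that each muscle's
regional features are learned separately and only then combined. Each
module has three paths — 1×1; 1×1 reduction (32 maps) then 3×3; 1×1
reduction then 5×5 — with 32 maps per path, concatenated to 96 maps and
max-pooled. The six module outputs concatenate channel-wise to 576
maps. The shared convolution block is six 3×3 convolutions with
VGG-style doubling widths (128, 128, 256, 256, 512, 512 by default,
configurable because small problems deserve small blocks), max pools
after convolutions 1, 2, 4 and 6, and a global max pool; a dense
softmax layer of width `n_classes` closes the network. Batch
normalization follows every convolution; dropout (rate 0.25) rides on
every max pool; Leaky ReLU (slope 0.01) is the activation throughout.
For spectral 36 × 36 inputs all operations are 2-D; for windowed
time-domain inputs the same topology runs in 1-D (kernels k × 1, the
feature columns on the channel axis).

**Baselines.** A VGG-style CNN (all widths halved, trailing blocks
dropped once the input's spatial extent is exhausted) and a
single-trunk inception network (channels concatenated first, one
inception stage, then the same convolution block). Both end in global
max pool + softmax.

**Engine.** The environment provides no R deep-learning framework, and
the architecture is the package's core subject, so training runs on a
self-contained engine: convolutions lower to im2col patch matrices and
BLAS GEMM; batch norm keeps running statistics for inference; dropout
is inverted; pooling uses floor semantics with first-match tie-breaks.
All layer gradients were verified against central finite differences
during development. Training is minibatch Adam (lr 1e-3, β = 0.9/0.999,
batch 16 by default) on categorical cross-entropy; optional early
stopping on validation loss is available via `patience` but off by
default so epoch counts are exact and runs are strictly reproducible
from the seed. Input features are standardized cell-wise with
training-set statistics stored on the model — the class-relevant
information is in the envelope *shape*, and standardization stops
large-magnitude features (VAR) from dominating early training.

**Splits.** The train/test split shuffles utterances across subjects
and sessions (the target is overall recognition ability, not
per-subject scores) and rounds the 80% training share half-up, so 101
items split 81/20.

## Transfer learning

Adaptation to a new subject fine-tunes a pretrained model on that
subject's first k sessions (chronological whole sessions, not random
utterances — the protocol counts adaptation data in sessions, and a
chronological split mimics deployment) and tests on the remaining
sessions. All layers are unfrozen by default at 0.1× the pretraining
learning rate; freezing by layer tag is available but not the default,
since with every class present in even one session the head alone is
rarely the bottleneck. The pretrained model is cloned, never mutated
(asserted by parameter checksum), its optimizer state is reset, and its
feature normalization is retained so new data enters the same input
space. Accuracy as a function of k is summarized by a fitted
logarithmic trendline `a·ln(k) + b`.

## Evaluation statistics

Accuracy is correct-over-total (the trace of the confusion matrix over
its sum). The per-class recognition rate is TP/(TP+FN) — recall. The
dispersion summary over classes uses the *population* standard
deviation: it describes the fixed set of classes at hand, not a sample
from a larger population. Classes absent from the test split have an
undefined rate; they are flagged and excluded from min/mean/SD rather
than erroring. The worst-k listing sorts ascending by rate with ties
broken by label index, and lists each class's misclassification targets
by descending wrong-label index.

## Problem sizes in tests and the acceptance script

The shipped experiments run on reduced problems chosen once: 10 classes
× 10 sessions × 1 subject (100 epochs, 80/20 split) for recognition,
separation 3 and noise sd 0.05 as the "well-separated, low-noise"
condition, and `separation = 0` with 30 sessions for the chance-level
check (a larger test set gives the binomial test resolution). Transfer
experiments pretrain on two subjects and adapt to a third with channel
gains shifted by 2.5×, fine-tuning on k ∈ {0, 1, 2, 4, 8} leading
sessions. Training-based experiments use the 1-D network on TD4
features: on this generator the class identity lives entirely in the
activation envelopes, which the windowed time-domain features capture
directly, and the 1-D topology is the cheap member of the family — the
2-D spectral path is exercised structurally (full graph audit, forward
passes, oracle-checked features) rather than through long training
runs.

## Known limitations

* The engine is CPU-only and single-process; it is sized for the
  package's experiments, not for corpus-scale training.
* Synthetic realism is deliberately limited (see above); no claim about
  accuracy on human sEMG follows from these experiments.
* The notch is fixed-frequency; line-frequency drift or harmonics are
  out of scope, as is artifact rejection beyond the two filters.
* Baseline classic ML models (LDA/RF/SVM) are not included; they are
  off-the-shelf fits with no bespoke computation and can be added as
  thin adapters.
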