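---
title: "Singing-voice separation and VIR remixing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Singing-voice separation and VIR remixing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cochlear implant (CI) users receive sound through 12–22 slowly modulated
spectral channels. That representation carries speech in quiet well, but it
degrades pitch and timbre badly, and music — where melody rides on spectral
and temporal fine structure — suffers most. One practical remedy is not to
make music simpler but to rebalance it: separate the lead singing voice from
the accompaniment and let the listener raise (or lower) the
vocals-to-instruments ratio (VIR), the power ratio of vocal to accompaniment
in dB. For that to work at a live event the separator must run in real time
with a latency small enough not to break audio-visual synchrony.

`voxsep` implements this processing chain end to end: STFT analysis and
overlap-add synthesis, a multilayer-perceptron (MLP) magnitude-spectrum
separator with its full training recipe, mixture-phase resynthesis, VIR
remixing under two level-adjustment modes, BSS-Eval quality metrics, a
synthetic scene generator with controllable room reverberation, and a
frame-streaming engine.

## Time–frequency front end

Analysis uses a 1024-sample periodic Hamming window with 75% overlap
(hop 256) at 44,100 Hz; dropping the redundant negative frequencies leaves
513 complex bins per frame. Synthesis inverts each frame, overlap-adds the
segments, and divides by the sum of the shifted analysis windows. Two
choices here are this package's own, because they are under-determined by
the processing chain itself:

* **Normalization.** The window is applied once, at analysis. For 75%
  overlap the shifted periodic Hamming windows sum to an exact constant
  (2.16), so dividing the overlap-added stream by the window sum gives
  perfect reconstruction. The implementation divides by the actual window
  sum sequence rather than the constant, so reconstruction stays exact for
  any hop, not only the default.
* **Edge handling.** The signal is zero-padded by `window_len - hop`
  samples at the start and up to one window at the end, so every input
  sample is covered by the full complement of overlapping frames; output is
  trimmed to the input length. This makes `istft(stft(x))` the identity to
  floating-point accuracy (the test suite asserts 1e-6 relative RMS;
  observed errors are ~1e-15), including at the edges.

Estimated sources are resynthesized from their predicted magnitude spectra
combined with the *mixture* phase. Mixture-phase resynthesis bounds
attainable quality (see "oracle separation" below) but requires no phase
model and costs nothing — both reasons it is standard in low-latency
separators.

## The separator

The network is deliberately small — an MLP, not a recurrent or
convolutional model — because the target is real-time use on modest
hardware:

* input: three consecutive magnitude frames (513 × 3 = 1539 units),
* one hidden layer of 1024 rectified-linear units,
* output: 1026 units — the vocal magnitude spectrum (first 513) and the
  instruments spectrum (second 513).

Training minimizes mean squared error on linear magnitude spectra of both
sources jointly, with Adam, mini-batches of 128 frame rows pooled across all
training chunks and reshuffled each epoch, initial learning rate 0.005
multiplied by 0.9 after every epoch, and dropout on the hidden layer
(training only, inverted scaling).

Several details are under-determined and were fixed as follows:

* **Loss.** MSE on linear magnitudes, summed over both source halves — the
  simplest choice consistent with magnitude regression.
* **Output non-negativity.** A rectifier at the output layer: the outputs
  are magnitude spectra, which are non-negative by definition. A
  configuration flag (`use_ratio_mask`) optionally converts the two outputs
  into a ratio mask `v/(v+i+eps)` applied to the mixture magnitude — a
  common alternative — without changing the default semantics.
* **Context direction.** The 3-frame context is causal: `[t-2, t-1, t]`
  predicts frame `t`. A centered context would add one hop of lookahead and
  contradict the declared one-hop algorithmic latency.
* **Feature scaling.** Inputs and targets are divided by a single scalar,
  the training set's 99th-percentile mixture magnitude, stored in the model
  and reapplied at inference. This keeps the rectifier units in a sensible
  operating range and must be persisted for the model to be usable.
* **Dropout probability.** "Dropout of 80%" is read literally as drop
  probability 0.8. Because the reading is ambiguous, the interpretation is
  switchable (`dropout_is_keep_prob`); the default follows the verbatim
  figure.
* **Shuffling unit.** Individual frame rows (not tracks) are pooled and
  shuffled each epoch, consistent with a batch size counted in frames.

Training is bit-deterministic given the seed: weight initialization,
shuffling and dropout all draw from one seeded stream, and the per-epoch
loss history is reproducible exactly. The Adam parameter update runs in a
small C kernel that updates the weight, moment and velocity buffers in
place; with ~2.6 M parameters this avoids re-allocating the full parameter
set on every mini-batch and keeps desk-scale training in the minutes range.

## VIR remixing

The remix control is a 25-position slider on a 1-dB grid from -12 to
+12 dB (`quantize_vir` rounds arbitrary values onto the grid, ties away
from zero). Two adjustment modes mirror the two ways the balance can be
changed in listening experiments:

* **vocals_gain** — instruments fixed, vocals scaled by `vir_db` dB:
  `m = 10^(vir/20) v + i`. The overall level varies with the slider.
* **balanced** — both sources move in opposite directions by half the VIR
  each: `m' = 10^(vir/40) v + 10^(-vir/40) i`, then the mix is rescaled so
  its RMS equals a calibrated reference exactly. The final rescaling is this
  package's choice: opposite gains alone keep the level only approximately
  constant (exactly, only for orthogonal equal-power sources), and a
  constant presentation level is the point of the mode. The reference is a
  configurable digital RMS (default 0.05 full scale) standing in for a
  sound-pressure calibration, which is a property of the playback chain the
  software cannot know.

## Quality metrics

`bss_decompose` implements the time-invariant (filter-length-1) BSS-Eval
family: the estimate is split into `s_target` (projection onto the true
target), `e_interf` (remainder of the projection onto the span of all true
sources) and `e_artif` (residual), giving SDR, SIR and SAR in dB. The
512-tap filtered variant is deliberately not implemented: the projection
form is exactly testable (the suite checks agreement with an independent
least-squares oracle to 1e-6 dB) and is sufficient for gating decisions.
Infinite ratios are capped at ±200 dB so that averages over tracks stay
finite; the cap is recorded in the result object.

The suitability gate used throughout (`cmd_evaluate`) is mean SDR above
0.69 dB and mean SAR above 4.42 dB for the vocal estimates — published
thresholds below which CI users begin to notice separation artifacts in
remixed pop music.

## Synthetic scenes

Real separation corpora cannot be redistributed with a package, so
`voxsep` generates its own study material. The generator's defaults are
fixed, stated here, and not tuned per experiment:

* **Vocal**: harmonic tone, per-note fundamental drawn log-uniformly from
  110–440 Hz, 5 Hz vibrato of ±50 cents, 12 harmonics with `1/h` decay and
  a gentle low-pass envelope (corner 4 kHz), syllabic notes of 0.4–1.2 s
  with 20 ms raised-cosine ramps and a 0.2 probability that a segment is a
  silent gap (emulating non-vocal passages, which are the hard case for a
  separator that must not hallucinate vocals). Voiced-region RMS 0.05.
* **Instruments**: percussive broadband bursts (~2 events/s, 50 ms decay),
  a harmonic bass line over 55–82 Hz fundamentals, three sustained chord
  partial stacks, and a -40 dB noise floor; overall RMS 0.05, so the
  default mix sits at 0 dB VIR.
* **Corpus**: 10 tracks of 30 s, cut into 30-s chunks, split 60/20/20 into
  train/validation/test *by track*, all seeded.

What the generator does **not** emulate: real vocal formant structure and
consonants, polyphonic accompaniment with shared harmonics in the vocal
band, production effects (compression, reverb on the stems), or genre
variety. Passing the quality gate on this material therefore shows that the
implementation — features, network, training loop, resynthesis, metrics —
is correct and that the architecture can learn a vocal/accompaniment
decomposition; it does not predict SDR on commercial music.

Rooms are modeled statistically: a unit direct impulse followed by a
seeded Gaussian tail with envelope `exp(-6.9078 t / T60)` (60 dB decay over
T60), scaled to a configurable direct-to-reverberant ratio (default +2 dB,
a plausible value a few meters from a PA in a mid-sized room). The two
study rooms use T60 = 0.65 s and 0.5 s; `estimate_reverb_time` recovers T60
from Schroeder backward integration with a -5…-35 dB linear fit, and the
suite requires recovery within 5%. A single-slope statistical RIR cannot
control T20 independently of T60 (both extrapolate from the same slope), so
early-decay metadata is carried but not matched — a documented limitation
of forgoing image-source modeling, which is out of scope. After rendering,
the ground truth for training and scoring is the *reverberant image* of
each source, matching how a microphone in the room would capture stems.

## Streaming and latency

The streaming engine consumes blocks of any size; each time one hop of new
input accumulates it analyzes one frame, runs the causal context through
the network, resynthesizes both sources with the frame's mixture phase,
applies the VIR gains in the spectral domain, and overlap-adds, emitting
exactly one hop of output per frame. The suite asserts equality with the
offline pipeline to 1e-9 for block sizes from 1 sample upward, including
random schedules.

Latency deserves precision. The *declared algorithmic latency* is the hop
duration — 256/44100 s ≈ 5.8 ms, reported as 6 ms — the time the scheme
must wait before it can process the next frame, and the figure exposed by
`algorithmic_latency_ms()` and the stream's latency report. On top of this
definition, overlap-add synthesis itself buffers: a sample is final only
once all four windows covering it have been synthesized, so the physical
delay from a sample entering to leaving the engine is `window_len - hop` to
`window_len` samples (17–23 ms at the defaults). Both figures are inherent
to any 75%-overlap OLA chain; the engine's emission schedule
(`floor(n/hop)*hop - (window_len - hop)` samples out after `n` in) is
asserted in the tests. Per-frame wall-clock processing times are logged and
summarized as a real-time factor but never test-asserted — they measure the
host, not the algorithm.

In balanced mode the stream applies the two opposite gains but not the
final RMS renormalization, which requires the whole signal; level constancy
in streaming is therefore approximate, and the offline/online equivalence
property is stated for the vocals-gain path.

## Problem sizes and test design

The package's own quality gate trains the full 1539–1024–1026 architecture
for 20 epochs on the 10-track synthetic corpus (about 31,000 training
frames) — enough for the loss schedule, shuffling, dropout and evaluation
chain to be exercised end to end at desk scale while the run stays in the
minutes range on one CPU. Unit tests use a 64-sample window at 8 kHz where
the property under test is configuration-independent (round-trip identity,
streaming equivalence, remix algebra), and the default 1024-sample window
where the published dimensions themselves are the property (513 bins, 1539
inputs, 1026 outputs). The band-disjoint fixture (vocal below 1 kHz,
accompaniment above 2 kHz) is the canary for the training loop: a correct
implementation separates it almost perfectly within 20 epochs, so
convergence failures point at the code, not the data.

## Known limitations

* Magnitude regression with mixture phase caps achievable SAR; the oracle
  (`ideal_magnitude_separation`) quantifies that ceiling per fixture.
* The balanced-mode RMS contract holds offline, not per-frame in streaming.
* WAV I/O covers 16/24-bit PCM and 32-bit float at a fixed rate;
  resampling is out of scope by design.
* The scene model is statistical; it controls T60 and direct-to-reverb
  ratio but not early reflections or source directivity.
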