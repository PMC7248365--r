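# voxsep

Real-time singing-voice separation and remixing for cochlear-implant (CI)
music listening, in R.

CI users hear music through 12–22 slowly modulated spectral channels, which
ruins pitch and timbre; listening tests consistently show they enjoy pop
music more when the lead vocal is boosted relative to the accompaniment.
`voxsep` implements the processing chain that makes this possible at a live
event: a low-latency source separator that splits a music mixture
`x(t) = y1(t) + y2(t)` into a vocal estimate and an instruments estimate,
and a remixer that recombines them at a user-chosen
**vocals-to-instruments ratio** (VIR, the vocal/accompaniment power ratio
in dB, on a 25-position slider from −12 to +12 dB).

## The method

* **Front end.** STFT with a 1024-sample periodic Hamming window, 75%
  overlap (hop 256) at 44.1 kHz → 513 complex bins per frame. Synthesis is
  overlap-add with window-sum normalization; `istft(stft(x))` reproduces
  `x` to floating-point accuracy.
* **Separator.** A multilayer perceptron mapping three consecutive
  magnitude frames (513 × 3 = 1539 inputs, causal context) through one
  1024-unit ReLU hidden layer to 1026 outputs — the vocal and instruments
  magnitude spectra. Training: MSE on linear magnitudes, Adam, batch 128,
  initial learning rate 0.005 ×0.9 per epoch, dropout 0.8 on the hidden
  layer, per-epoch reshuffling, all bit-reproducible from a seed.
* **Resynthesis.** Estimated magnitudes are combined with the *mixture*
  phase and inverted (`resynthesize_with_mixture_phase`).
* **Remix.** `vocals_gain` mode scales the vocals only
  (`m = 10^(VIR/20) v + i`); `balanced` mode moves both sources in opposite
  directions by VIR/2 dB and renormalizes to a calibrated RMS so the
  presentation level is constant.
* **Metrics.** Time-invariant BSS-Eval: the estimate is decomposed into
  `s_target + e_interf + e_artif` by orthogonal projection onto the true
  sources, giving SDR, SIR and SAR in dB. The suitability gate for CI
  remixing is mean SDR > 0.69 dB and mean SAR > 4.42 dB.
* **Streaming.** A frame-streaming engine (`stream_init` / `push_block` /
  `flush`) consumes arbitrary block sizes, emits one hop of output per
  frame, matches the offline pipeline to 1e−9, and reports its declared
  algorithmic latency — one hop, 256/44100 s ≈ 6 ms.
* **Synthetic scenes.** Because separation corpora cannot ship with a
  package, `voxsep` generates its own: harmonic vocals with vibrato and
  silent passages, percussive/bass/chord accompaniment, 30-s tracks split
  60/20/20 by track, and statistical room impulse responses with controlled
  T60 (0.65 s and 0.5 s study rooms) validated by Schroeder backward
  integration.

## Worked example

```r
library(voxsep)

# one synthetic 10-s track
vocal   <- gen_vocal(10, seed = 1)
backing <- gen_instruments(10, seed = 2)
pair    <- source_pair(vocal, backing, id = "demo")

cfg <- stft_config()
lat <- algorithmic_latency_ms(cfg, 44100)
cat(sprintf("algorithmic latency: %.3f ms (reported as %d ms)\n",
            lat$ms, lat$rounded))
#> algorithmic latency: 5.805 ms (reported as 6 ms)

# oracle separation: true magnitudes + mixture phase — the upper bound of
# any magnitude-domain separator under mixture-phase resynthesis
oracle <- ideal_magnitude_separation(pair, cfg)
evaluate_pair(oracle, pair)
#>        source    sdr_db   sir_db   sar_db
#> 1       vocal 11.526783 19.12435 12.40915
#> 2 instruments  8.800869 12.56361 11.40428
#> 3        mean 10.163826 15.84398 11.90671

# remix at +8 dB VIR with constant presentation level
remix <- apply_vir(oracle$vocal, oracle$instruments,
                   vir_setting(8, "balanced", reference_rms = 0.05))
signal_rms(remix)
#> [1] 0.05
```

The oracle SDR (~10 dB mean here) is the ceiling imposed by mixture-phase
resynthesis on this material; a trained model approaches it from below. To
train one:

```r
split <- build_corpus(n_tracks = 10, duration = 30, seed = 0)   # 6/2/2 split
fit   <- train_separator(split$train, train_config(epochs = 20, seed = 0))
ev    <- cmd_evaluate(fit$model, split)    # per-chunk SDR/SIR/SAR + gate
```

A command-line front end wrapping the same functions lives in
`inst/cli/voxsep.R`:

```sh
Rscript inst/cli/voxsep.R simulate --out-dir corpus --n-tracks 10 --seed 0
Rscript inst/cli/voxsep.R train    --corpus-dir corpus --epochs 20
Rscript inst/cli/voxsep.R stream   --model corpus/model.rds \
        --in-wav corpus/track01_mixture.wav --out-wav remix.wav --vir-db 8
```

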