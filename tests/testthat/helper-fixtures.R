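# Shared fixtures. Expensive trained models are cached so several test
# files (and the acceptance suite) reuse a single training run.

.fixture_cache <- new.env(parent = emptyenv())

# Small analysis config for cheap unit tests.
small_cfg <- function() stft_config(64)
small_rate <- 8000

# Orthogonal equal-power source pair: sine and cosine at an exact
# half-period count are orthogonal over the full window.
orthogonal_pair <- function(n = 4000, rate = small_rate, amp = 0.1) {
  t <- seq_len(n) - 1L
  v <- amp * sin(2 * pi * 100 * t / rate)
  i <- amp * cos(2 * pi * 100 * t / rate)
  source_pair(audio_signal(v, rate), audio_signal(i, rate), id = "ortho")
}

random_signal <- function(n, rate = small_rate, seed = 1, amp = 0.1) {
  set.seed(seed)
  audio_signal(amp * rnorm(n), rate)
}

# A random-weight (untrained but finite) model, marked usable, for
# plumbing and equivalence tests that do not need separation quality.
random_model <- function(bins, hidden = 12, seed = 2) {
  m <- separator_model(bins = bins, hidden = hidden, seed = seed)
  m$trained <- TRUE
  m
}

# --- disjoint-band training fixture (shared run) ---------------------------
# Vocal band-limited below 1 kHz, instruments above 2 kHz; 20 epochs,
# seed 0, default 1024-sample STFT at 44.1 kHz.
fixture_disjoint_run <- function() {
  if (!is.null(.fixture_cache$disjoint)) return(.fixture_cache$disjoint)
  train_pairs <- lapply(1:3, function(i) gen_disjoint_pair(8, seed = i))
  test_pairs <- lapply(8:9, function(i) gen_disjoint_pair(6, seed = i))
  fit <- train_separator(train_pairs, train_config(epochs = 20, seed = 0),
                         stft_config(), hidden = 1024)
  .fixture_cache$disjoint <- list(fit = fit, train = train_pairs,
                                  test = test_pairs)
  .fixture_cache$disjoint
}

# --- benchmark-gate fixture (shared run) -----------------------------------
# 10-track 30-s synthetic corpus, 60/20/20 split, seed 0; the separator
# trained with the published architecture and optimizer settings for 20
# epochs; evaluated on the held-out test mixtures.
fixture_benchmark_run <- function(seed = 0) {
  key <- paste0("bench_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  split <- build_corpus(n_tracks = 10, duration = 30, seed = 0)
  fit <- train_separator(split$train,
                         train_config(epochs = 20, seed = seed),
                         stft_config(), hidden = 1024)
  ev <- cmd_evaluate(fit$model, split)
  .fixture_cache[[key]] <- list(split = split, fit = fit, eval = ev)
  .fixture_cache[[key]]
}

# Independent convolution reference (base R).
fft_conv_ref <- function(x, h) stats::convolve(x, rev(h), type = "open")

# Independent BSS-Eval oracle built on qr() least squares: target part from
# a single-regressor fit, full-span part from the two-regressor fit.
bss_oracle <- function(e, s1, s2, target = 1) {
  S <- cbind(s1, s2)
  tgt <- S[, target]
  s_target <- qr.fitted(qr(cbind(tgt)), e)
  p_all <- qr.fitted(qr(S), e)
  e_interf <- p_all - s_target
  e_artif <- e - p_all
  cap <- function(num, den) {
    if (den <= 0) return(200)
    min(max(10 * log10(num / den), -200), 200)
  }
  list(sdr = cap(sum(s_target^2), sum((e_interf + e_artif)^2)),
       sir = cap(sum(s_target^2), sum(e_interf^2)),
       sar = cap(sum((s_target + e_interf)^2), sum(e_artif^2)))
}
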