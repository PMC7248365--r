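# Time-frequency analysis/synthesis and latency accounting.

test_that("stft frame dimension is window_len/2 + 1", {
  x <- random_signal(44100, rate = 44100)
  sp <- stft(x, stft_config())
  expect_equal(nrow(sp$z), 513L)
  for (wl in c(8L, 64L, 256L)) {
    expect_equal(nrow(stft(random_signal(1000), stft_config(wl))$z),
                 wl / 2L + 1L)
  }
})

test_that("stft of silence is exactly zero and empty input errors", {
  sp <- stft(audio_signal(numeric(small_rate), small_rate), small_cfg())
  expect_true(all(sp$z == 0))
  expect_error(stft(audio_signal(numeric(0))), "empty")
  expect_error(stft_config(64, 100), "hop")
  expect_error(stft_config(63), "even")
  expect_error(audio_signal(c(1, NaN)), "finite")
})

test_that("bin-centered cosine peaks at its bin, matching a direct DFT oracle", {
  cfg <- small_cfg()
  rate <- small_rate
  f <- 10 * rate / cfg$window_len
  n <- 4000
  x <- cos(2 * pi * f * (0:(n - 1)) / rate)
  sp <- stft(audio_signal(x, rate), cfg)
  interior <- 10:(ncol(sp$z) - 10)
  peaks <- apply(abs(sp$z[, interior]), 2, which.max)
  expect_true(all(peaks == 11L))  # bin 10, 1-based index 11

  # direct DFT oracle on a few interior frames of the padded signal
  pre <- cfg$window_len - cfg$hop
  padded <- c(numeric(pre), x)
  for (k in c(20L, 57L)) {
    seg <- padded[(k - 1L) * cfg$hop + seq_len(cfg$window_len)] * cfg$window
    nn <- 0:(cfg$window_len - 1L)
    oracle <- vapply(0:(cfg$window_len / 2), function(b) {
      sum(seg * exp(-2i * pi * b * nn / cfg$window_len))
    }, complex(1))
    expect_equal(sp$z[, k], oracle, tolerance = 1e-12)
  }
})

test_that("istft(stft(x)) is the identity for random signals and configs", {
  for (case in list(list(n = 64, wl = 64), list(n = 500, wl = 64),
                    list(n = 1000, wl = 128), list(n = 777, wl = 64),
                    list(n = 3000, wl = 256))) {
    x <- random_signal(case$n, seed = case$n + case$wl)
    cfg <- stft_config(case$wl)
    y <- istft(stft(x, cfg))
    expect_equal(length(y$samples), case$n)
    rel <- signal_rms(y$samples - x$samples) / signal_rms(x)
    expect_lt(rel, 1e-6)
  }
  # non-default overlap still reconstructs (normalizer is not constant)
  x <- random_signal(2000, seed = 9)
  cfg <- stft_config(64, 24)
  rel <- signal_rms(istft(stft(x, cfg))$samples - x$samples) / signal_rms(x)
  expect_lt(rel, 1e-6)
})

test_that("round trip on a 30-s synthetic mixture is sample-accurate", {
  pair <- source_pair(gen_vocal(30, seed = 11, rate = small_rate),
                      gen_instruments(30, seed = 12, rate = small_rate))
  y <- istft(stft(pair$mixture, small_cfg()))
  expect_lt(max(abs(y$samples - pair$mixture$samples)), 1e-5)
})

test_that("stft is linear", {
  x <- random_signal(1500, seed = 1)
  y <- random_signal(1500, seed = 2)
  cfg <- small_cfg()
  lhs <- stft(audio_signal(0.3 * x$samples - 1.7 * y$samples, small_rate), cfg)$z
  rhs <- 0.3 * stft(x, cfg)$z - 1.7 * stft(y, cfg)$z
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-9)
})

test_that("frame energy obeys a Parseval relation with windowed segments", {
  cfg <- small_cfg()
  x <- random_signal(2000, seed = 4)
  sp <- stft(x, cfg)
  pre <- cfg$window_len - cfg$hop
  padded <- c(numeric(pre), x$samples,
              numeric((ncol(sp$z) - 1L) * cfg$hop + cfg$window_len -
                        pre - length(x$samples)))
  wl <- cfg$window_len
  for (k in c(5L, 40L)) {
    seg <- padded[(k - 1L) * cfg$hop + seq_len(wl)] * cfg$window
    # energy of full two-sided spectrum = wl * time energy; reconstruct the
    # two-sided energy from the one-sided frame
    z <- sp$z[, k]
    full_e <- sum(abs(z)^2) + sum(abs(z[2:(wl / 2)])^2)
    expect_equal(full_e / wl, sum(seg^2), tolerance = 1e-6)
  }
})

test_that("mixture-phase resynthesis: own magnitude is the identity, zero is silence", {
  x <- random_signal(2500, seed = 6)
  cfg <- small_cfg()
  sp <- stft(x, cfg)
  back <- resynthesize_with_mixture_phase(magnitude(sp), sp)
  expect_lt(signal_rms(back$samples - x$samples) / signal_rms(x), 1e-6)

  zero_mag <- magnitude(sp)
  zero_mag$m[] <- 0
  expect_true(all(resynthesize_with_mixture_phase(zero_mag, sp)$samples == 0))

  wrong <- magnitude(stft(random_signal(500, seed = 1), cfg))
  expect_error(resynthesize_with_mixture_phase(wrong, sp), "shape")
})

test_that("true-magnitude resynthesis with mixture phase separates disjoint bands", {
  pair <- gen_disjoint_pair(2, seed = 3, rate = 44100)
  est <- ideal_magnitude_separation(pair, stft_config())
  r <- bss_decompose(est$vocal, list(pair$vocal, pair$instruments), 1)
  expect_gt(r$sdr_db, 15)
})

test_that("algorithmic latency follows hop duration", {
  lat <- algorithmic_latency_ms(stft_config(), 44100)
  expect_equal(lat$ms, 256 / 44100 * 1000, tolerance = 1e-12)
  expect_identical(lat$rounded, 6L)
  expect_equal(algorithmic_latency_ms(stft_config(1024, 441), 44100)$ms, 10)
  lat512 <- algorithmic_latency_ms(stft_config(1024, 512), 44100)
  expect_equal(lat512$ms, 512 / 44100 * 1000, tolerance = 1e-12)
  expect_identical(lat512$rounded, 12L)
  expect_error(algorithmic_latency_ms(stft_config(), -1), "positive")
})

test_that("WAV files round-trip at every supported depth", {
  x <- random_signal(3000, rate = 44100, seed = 8)
  for (depth in c(16, 24, 32)) {
    path <- withr::local_tempfile(fileext = ".wav")
    write_wav(x, path, depth)
    y <- read_wav(path)
    expect_equal(y$rate, 44100)
    tol <- if (depth == 32) 1e-7 else 2^-(depth - 2)
    expect_lt(max(abs(y$samples - x$samples)), tol)
  }
  expect_error(suppressWarnings(read_wav(withr::local_tempfile(
    fileext = ".wav"), TRUE)))
})

test_that("stereo WAVs downmix to the channel mean", {
  # hand-build a 2-channel 16-bit file: interleaved L/R
  path <- withr::local_tempfile(fileext = ".wav")
  l <- c(0.5, -0.5, 0.25, 0)
  r <- c(0.1, 0.3, -0.25, 0)
  inter <- as.vector(rbind(l, r))
  con <- file(path, "wb")
  q <- as.integer(round(inter * 32767))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(q)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(q)), con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  close(con)
  y <- read_wav(path)
  expect_equal(y$samples, (l + r) / 2, tolerance = 1e-4)
  ch <- read_wav(path, downmix = FALSE)
  expect_length(ch, 2)
  expect_equal(ch[[2]]$samples, r, tolerance = 1e-4)
  expect_error(read_wav(path, expected_rate = 44100), "rate")
})
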