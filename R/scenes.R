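#' Parameters of the synthetic singing-voice generator
#'
#' The generator emulates the salient features of the vocal stems in
#' separation corpora: a harmonic tone with a per-note fundamental drawn
#' from a musical range, slow vibrato, a gently low-passed harmonic
#' envelope, and syllabic on/off gating including silent (non-vocal)
#' passages.
#'
#' @param f0_min,f0_max Fundamental-frequency range in Hz (default
#'   110-440, roughly A2-A4).
#' @param vibrato_rate Vibrato rate in Hz (default 5).
#' @param vibrato_cents Peak vibrato depth in cents (default 50).
#' @param n_harmonics Number of harmonics (default 12; harmonics above
#'   90% of Nyquist are muted).
#' @param gap_prob Probability that a syllabic segment is a silent gap
#'   (default 0.2) — emulates non-vocal time passages.
#' @param note_s Range of note/gap segment durations in seconds.
#' @param rolloff_hz Corner of the `1/(1 + (f/rolloff)^2)` spectral
#'   envelope applied on top of the `1/h` harmonic decay (default 4000).
#' @param level_rms Target RMS of the voiced portions (default 0.05).
#' @return An object of class `vocal_params`.
#' @export
vocal_params <- function(f0_min = 110, f0_max = 440, vibrato_rate = 5,
                         vibrato_cents = 50, n_harmonics = 12,
                         gap_prob = 0.2, note_s = c(0.4, 1.2),
                         rolloff_hz = 4000, level_rms = 0.05) {
  stopifnot(f0_min > 0, f0_max >= f0_min, gap_prob >= 0, gap_prob <= 1,
            n_harmonics >= 1, level_rms > 0)
  structure(list(f0_min = f0_min, f0_max = f0_max,
                 vibrato_rate = vibrato_rate, vibrato_cents = vibrato_cents,
                 n_harmonics = as.integer(n_harmonics), gap_prob = gap_prob,
                 note_s = note_s, rolloff_hz = rolloff_hz,
                 level_rms = level_rms),
            class = "vocal_params")
}

#' Parameters of the synthetic accompaniment generator
#'
#' Stands in for the instrumental stems (bass, drums, other): percussive
#' broadband bursts, a harmonic bass line, sustained chord partials and a
#' low noise floor.
#'
#' @param burst_rate Mean percussive events per second (default 2).
#' @param burst_decay_s Exponential decay constant of each burst (default
#'   0.05 s).
#' @param bass_f0 Candidate bass fundamentals in Hz (default
#'   `c(55, 62, 73, 82)`).
#' @param chord_hz Sustained chord partial roots in Hz (default
#'   `c(220, 277, 330)`).
#' @param noise_floor_db Broadband noise floor relative to the overall
#'   level in dB (default -40).
#' @param level_rms Target overall RMS (default 0.05).
#' @return An object of class `instrument_params`.
#' @export
instrument_params <- function(burst_rate = 2, burst_decay_s = 0.05,
                              bass_f0 = c(55, 62, 73, 82),
                              chord_hz = c(220, 277, 330),
                              noise_floor_db = -40, level_rms = 0.05) {
  stopifnot(burst_rate >= 0, burst_decay_s > 0, all(bass_f0 >= 0),
            level_rms > 0)
  structure(list(burst_rate = burst_rate, burst_decay_s = burst_decay_s,
                 bass_f0 = bass_f0, chord_hz = chord_hz,
                 noise_floor_db = noise_floor_db, level_rms = level_rms),
            class = "instrument_params")
}

# Draw a syllabic note/gap segmentation; returns per-sample base f0
# (0 = gap). Assumes an active RNG stream.
draw_f0_contour <- function(n, rate, params) {
  f0 <- numeric(n)
  pos <- 0L
  while (pos < n) {
    seg_n <- as.integer(round(stats::runif(1, params$note_s[1],
                                           params$note_s[2]) * rate))
    seg_n <- min(max(seg_n, 1L), n - pos)
    is_gap <- stats::runif(1) < params$gap_prob
    if (!is_gap) {
      f <- 2^stats::runif(1, log2(params$f0_min), log2(params$f0_max))
      f0[pos + seq_len(seg_n)] <- f
    }
    pos <- pos + seg_n
  }
  f0
}

# Raised-cosine on/off envelope with `ramp_s` attack/release around the
# voiced regions of a contour.
gate_envelope <- function(voiced, rate, ramp_s = 0.02) {
  n <- length(voiced)
  env <- as.numeric(voiced)
  r <- max(2L, as.integer(round(ramp_s * rate)))
  ramp <- (1 - cos(pi * seq_len(r) / r)) / 2
  edges <- diff(c(0, env, 0))
  on <- which(edges == 1)
  off <- which(edges == -1) - 1L
  for (s in on) {
    i <- s:min(s + r - 1L, n)
    env[i] <- pmin(env[i], ramp[seq_along(i)])
  }
  for (s in off) {
    i <- max(s - r + 1L, 1L):s
    env[i] <- pmin(env[i], rev(ramp)[seq_along(i) + (r - length(i))])
  }
  env
}

#' Generate a synthetic singing-voice signal
#'
#' Deterministic given `seed`. The per-sample base fundamental contour
#' (0 during gaps) is attached as attribute `"f0_base"` for downstream
#' validation (see [measure_harmonicity()]).
#'
#' @param duration Duration in seconds (> 0).
#' @param params A [vocal_params()].
#' @param seed Integer seed.
#' @param rate Sampling rate (default 44100).
#' @return An [audio_signal()].
#' @export
gen_vocal <- function(duration, params = vocal_params(), seed = 1,
                      rate = 44100) {
  stopifnot(duration > 0)
  n <- as.integer(round(duration * rate))
  with_seed(seed, {
    f0 <- draw_f0_contour(n, rate, params)
    voiced <- f0 > 0
    if (!any(voiced)) {
      out <- audio_signal(numeric(n), rate)
      attr(out, "f0_base") <- f0
      return(out)
    }
    vib_phase <- stats::runif(1, 0, 2 * pi)
    t <- (seq_len(n) - 1L) / rate
    f_inst <- f0 * 2^((params$vibrato_cents / 1200) *
                        sin(2 * pi * params$vibrato_rate * t + vib_phase))
    phi <- 2 * pi * cumsum(f_inst) / rate
    env <- gate_envelope(voiced, rate)
    x <- numeric(n)
    for (h in seq_len(params$n_harmonics)) {
      fh <- h * f_inst
      a <- (1 / h) / (1 + (h * f0 / params$rolloff_hz)^2)
      a[fh > 0.45 * rate] <- 0
      x <- x + a * sin(h * phi + stats::runif(1, 0, 2 * pi))
    }
    x <- x * env
    r <- sqrt(mean(x[voiced]^2))
    if (r > 0) x <- x * (params$level_rms / r)
    out <- audio_signal(x, rate)
    attr(out, "f0_base") <- f0
    out
  })
}

#' Generate a synthetic instrumental accompaniment
#'
#' Percussive noise bursts, a harmonic bass line, sustained chord
#' partials and a broadband noise floor; deterministic given `seed`.
#'
#' @param duration Duration in seconds (> 0).
#' @param params An [instrument_params()].
#' @param seed Integer seed.
#' @param rate Sampling rate (default 44100).
#' @return An [audio_signal()].
#' @export
gen_instruments <- function(duration, params = instrument_params(),
                            seed = 1, rate = 44100) {
  stopifnot(duration > 0)
  n <- as.integer(round(duration * rate))
  with_seed(seed, {
    t <- (seq_len(n) - 1L) / rate

    perc <- numeric(n)
    if (params$burst_rate > 0) {
      n_ev <- stats::rpois(1, params$burst_rate * duration)
      if (n_ev > 0) {
        starts <- sort(as.integer(stats::runif(n_ev, 1, n)))
        blen <- as.integer(round(4 * params$burst_decay_s * rate))
        decay <- exp(-(seq_len(blen) - 1L) / (params$burst_decay_s * rate))
        for (s in starts) {
          i <- s:min(s + blen - 1L, n)
          perc[i] <- perc[i] + stats::rnorm(length(i)) * decay[seq_along(i)]
        }
      }
    }

    bass <- numeric(n)
    if (length(params$bass_f0) && any(params$bass_f0 > 0)) {
      f0b <- numeric(n); pos <- 0L
      while (pos < n) {
        seg <- min(as.integer(round(stats::runif(1, 0.5, 1) * rate)), n - pos)
        f0b[pos + seq_len(seg)] <- sample(params$bass_f0, 1)
        pos <- pos + seg
      }
      phib <- 2 * pi * cumsum(f0b) / rate
      for (h in 1:5) {
        bass <- bass + (1 / h) * sin(h * phib + stats::runif(1, 0, 2 * pi))
      }
    }

    chords <- numeric(n)
    if (length(params$chord_hz)) {
      lfo <- 1 + 0.3 * sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi))
      for (f in params$chord_hz) {
        for (h in 1:4) {
          if (h * f < 0.45 * rate) {
            chords <- chords +
              (1 / h^1.5) * sin(2 * pi * h * f * t + stats::runif(1, 0, 2 * pi))
          }
        }
      }
      chords <- chords * lfo
    }

    floor_amp <- 10^(params$noise_floor_db / 20)
    noise <- stats::rnorm(n) * floor_amp

    unit <- function(x) if (any(x != 0)) x / sqrt(mean(x^2)) else x
    x <- 1.0 * unit(perc) + 0.8 * unit(bass) + 0.6 * unit(chords) + noise
    if (any(x != 0)) x <- x * (params$level_rms / sqrt(mean(x^2)))
    audio_signal(x, rate)
  })
}

#' Generate a band-disjoint vocal/instruments fixture
#'
#' A deliberately easy separation problem for capacity and upper-bound
#' tests: the vocal is harmonic with all energy below `split_low` Hz and
#' the accompaniment is a sum of sustained and percussively gated
#' partials entirely above `split_high` Hz.
#'
#' @param duration Duration in seconds.
#' @param seed Integer seed.
#' @param rate Sampling rate (default 44100).
#' @param split_low Upper band edge of the vocal (default 1000 Hz).
#' @param split_high Lower band edge of the instruments (default 2000 Hz).
#' @param level_rms Per-source RMS (default 0.05).
#' @return A [source_pair()].
#' @export
gen_disjoint_pair <- function(duration, seed = 1, rate = 44100,
                              split_low = 1000, split_high = 2000,
                              level_rms = 0.05) {
  seeds <- derive_seeds(seed, 2)
  vp <- vocal_params(f0_min = 200, f0_max = 235, n_harmonics = 4,
                     vibrato_cents = 20, level_rms = level_rms)
  # 4 harmonics of <= 235 Hz (+20 cents vibrato) stay below 960 Hz
  vocal <- gen_vocal(duration, vp, seed = seeds[1], rate = rate)

  n <- as.integer(round(duration * rate))
  instruments <- with_seed(seeds[2], {
    t <- (seq_len(n) - 1L) / rate
    freqs <- stats::runif(8, split_high + 500, min(9000, 0.4 * rate))
    x <- numeric(n)
    for (f in freqs[1:4]) {          # sustained partials
      x <- x + sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
    gate <- numeric(n)               # percussive gating for the rest
    n_ev <- stats::rpois(1, 3 * duration)
    blen <- as.integer(round(0.12 * rate))
    decay <- exp(-(seq_len(blen) - 1L) / (0.03 * rate))
    if (n_ev > 0) {
      for (s in sort(as.integer(stats::runif(n_ev, 1, n)))) {
        i <- s:min(s + blen - 1L, n)
        gate[i] <- pmax(gate[i], decay[seq_along(i)])
      }
    }
    for (f in freqs[5:8]) {
      x <- x + gate * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
    x * (level_rms / sqrt(mean(x^2)))
  })
  source_pair(vocal, audio_signal(instruments, rate),
              id = sprintf("disjoint_%d", seed))
}

#' Measure the harmonic energy fraction of a generated vocal
#'
#' Validates the vocal generator: the fraction of short-time spectral
#' energy lying in bands around the harmonics of the known fundamental
#' contour. Bands span +/- the vibrato depth in cents, widened by the
#' vibrato rate and a few DFT bins to cover modulation sidebands and
#' window mainlobe leakage. Frames containing note boundaries or gaps are
#' excluded.
#'
#' @param x A signal from [gen_vocal()] (must carry the `"f0_base"`
#'   attribute) or any [audio_signal()] with `f0_base` supplied.
#' @param f0_base Per-sample fundamental contour (0 = unvoiced); taken
#'   from the attribute when omitted.
#' @param params The [vocal_params()] used to generate the signal.
#' @param nfft Analysis frame length (default 8192).
#' @return Mean harmonic-band energy fraction over analyzed frames.
#' @export
measure_harmonicity <- function(x, f0_base = attr(x, "f0_base"),
                                params = vocal_params(), nfft = 8192) {
  x <- as_audio(x)
  if (is.null(f0_base)) stop("no f0 contour available")
  s <- x$samples
  rate <- x$rate
  hop <- nfft %/% 4L
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nfft - 1L)) / nfft)
  starts <- seq(1L, length(s) - nfft + 1L, by = hop)
  ratios <- c()
  half_bw_extra <- params$vibrato_rate + 4 * rate / nfft
  for (st in starts) {
    idx <- st:(st + nfft - 1L)
    f0w <- f0_base[idx]
    if (any(f0w == 0) || max(f0w) - min(f0w) > 1e-9) next  # gap or boundary
    f0 <- f0w[1]
    spec <- abs(stats::fft(s[idx] * w))[seq_len(nfft %/% 2L + 1L)]
    freqs <- (seq_along(spec) - 1L) * rate / nfft
    p <- spec^2
    total <- sum(p[-1])
    if (total <= 0) next
    inband <- rep(FALSE, length(p))
    up <- 2^(params$vibrato_cents / 1200)
    for (h in seq_len(params$n_harmonics)) {
      lo <- h * f0 / up - half_bw_extra
      hi <- h * f0 * up + half_bw_extra
      inband <- inband | (freqs >= lo & freqs <= hi)
    }
    inband[1] <- FALSE
    ratios <- c(ratios, sum(p[inband]) / total)
  }
  if (!length(ratios)) stop("no steady voiced frames to analyze")
  mean(ratios)
}

# ---------------------------------------------------------------------------
# Room simulation: statistical impulse responses with a controlled T60.
# ---------------------------------------------------------------------------

#' Room scene configuration
#'
#' The room is modeled statistically: a direct impulse followed by an
#' exponentially decaying noise tail whose envelope drops 60 dB over
#' `t60` seconds. Geometric room parameters (dimensions, damping,
#' reflection coefficients) can be carried as metadata but do not affect
#' the rendering.
#'
#' @param t60 Reverberation time in seconds (> 0).
#' @param direct_to_reverb_db Direct-to-reverberant energy ratio in dB
#'   (default 2).
#' @param rir_s Impulse-response length in seconds (default `1.5 * t60`).
#' @param seed Seed for the noise tail.
#' @param metadata Optional list of descriptive room properties.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(t60, direct_to_reverb_db = 2, rir_s = 1.5 * t60,
                         seed = 1, metadata = list()) {
  stopifnot(t60 > 0, rir_s >= t60)
  structure(list(t60 = t60, direct_to_reverb_db = direct_to_reverb_db,
                 rir_s = rir_s, seed = seed, metadata = metadata),
            class = "scene_config")
}

#' Synthesize a room impulse response
#'
#' Direct impulse plus a seeded Gaussian noise tail with envelope
#' `exp(-6.9078 * t / t60)` (60 dB decay over `t60`), scaled to the
#' configured direct-to-reverberant energy ratio.
#'
#' @param scene A [scene_config()].
#' @param rate Sampling rate (default 44100).
#' @return An [audio_signal()] with the scene attached as attribute
#'   `"scene"`.
#' @export
make_rir <- function(scene, rate = 44100) {
  stopifnot(inherits(scene, "scene_config"))
  n <- as.integer(round(scene$rir_s * rate))
  t <- (seq_len(n - 1L)) / rate
  tail <- with_seed(scene$seed, stats::rnorm(n - 1L)) *
    exp(-6.9078 * t / scene$t60)
  g <- sqrt(10^(-scene$direct_to_reverb_db / 10) / sum(tail^2))
  h <- c(1, g * tail)
  out <- audio_signal(h, rate)
  attr(out, "scene") <- scene
  out
}

#' Direct-to-reverberant energy ratio of an impulse response
#'
#' @param rir An [audio_signal()] impulse response.
#' @param direct_ms Window after the onset counted as direct sound
#'   (default 2.5 ms).
#' @return Ratio in dB.
#' @export
direct_to_reverb_db <- function(rir, direct_ms = 2.5) {
  rir <- as_audio(rir)
  h <- rir$samples
  k <- max(1L, as.integer(round(direct_ms / 1000 * rir$rate)))
  ratio_db(sum(h[seq_len(min(k, length(h)))]^2),
           sum(h[-seq_len(min(k, length(h)))]^2))
}

#' Estimate the reverberation time of an impulse response
#'
#' Schroeder backward integration of the squared impulse response,
#' followed by a linear fit of the energy-decay curve over the -5 to
#' -35 dB range, extrapolated to 60 dB of decay.
#'
#' @param rir An [audio_signal()] impulse response.
#' @return Estimated T60 in seconds.
#' @export
estimate_reverb_time <- function(rir) {
  rir <- as_audio(rir)
  h <- rir$samples
  if (!any(h != 0)) stop("silent impulse response")
  edc <- rev(cumsum(rev(h^2)))
  db <- 10 * log10(edc / edc[1])
  sel <- which(db <= -5 & db >= -35)
  if (length(sel) < 10L || min(db, na.rm = TRUE) > -35) {
    stop("decay range not reached: cannot fit -5..-35 dB slope")
  }
  t <- (sel - 1L) / rir$rate
  fit <- stats::lm.fit(cbind(1, t), db[sel])
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0) stop("non-decaying energy curve")
  as.numeric(-60 / slope)
}

fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  m <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - length(x)))) *
                       stats::fft(c(h, numeric(m - length(h)))),
                     inverse = TRUE)) / m
  y[seq_len(n)]
}

#' Render a source pair in a room
#'
#' Convolves each source with the impulse response; the ground truth for
#' training and evaluation is the *reverberant image* of each source, and
#' the mixture is the sum of the two images. Outputs are trimmed to the
#' original duration.
#'
#' @param pair A [source_pair()].
#' @param rir An [audio_signal()] impulse response (see [make_rir()]).
#' @return A reverberant [source_pair()].
#' @export
render_scene <- function(pair, rir) {
  stopifnot(inherits(pair, "source_pair"))
  rir <- as_audio(rir)
  stopifnot_same_rate(pair$mixture, rir)
  n <- length(pair$vocal$samples)
  v <- fft_convolve(pair$vocal$samples, rir$samples)[seq_len(n)]
  i <- fft_convolve(pair$instruments$samples, rir$samples)[seq_len(n)]
  source_pair(audio_signal(v, rir$rate), audio_signal(i, rir$rate),
              id = paste0(pair$id, "_rev"))
}

#' Build a synthetic training corpus
#'
#' Generates `n_tracks` vocal/instruments pairs (optionally rendered in a
#' reverberant room), chunks them and splits them into train/validation/
#' test sets by track. Fully reproducible from `seed`. When `dir` is
#' given, chunk WAVs (32-bit float) and a JSON manifest capturing every
#' parameter and seed are written there.
#'
#' @param n_tracks Number of tracks (>= 5).
#' @param duration Track duration in seconds (default 30).
#' @param scene Optional [scene_config()] for reverberant rendering.
#' @param fractions Split fractions (default 0.6/0.2/0.2).
#' @param chunk_s Chunk length in seconds (default 30).
#' @param seed Master seed.
#' @param rate Sampling rate (default 44100).
#' @param vparams,iparams Generator parameter objects.
#' @param dir Optional output directory for WAV fixtures + manifest.
#' @return A `dataset_split` (see [chunk_and_split()]); when `dir` is
#'   given the manifest path is attached as attribute `"manifest"`.
#' @export
build_corpus <- function(n_tracks = 10, duration = 30, scene = NULL,
                         fractions = c(train = 0.6, validation = 0.2,
                                       test = 0.2),
                         chunk_s = 30, seed = 0, rate = 44100,
                         vparams = vocal_params(),
                         iparams = instrument_params(), dir = NULL) {
  if (n_tracks < 5) stop("need at least 5 tracks for a 3-way split")
  seeds <- derive_seeds(seed, 2L * n_tracks + 2L)
  rir <- if (!is.null(scene)) {
    sc <- scene; sc$seed <- seeds[2L * n_tracks + 2L]
    make_rir(sc, rate)
  }
  tracks <- lapply(seq_len(n_tracks), function(i) {
    v <- gen_vocal(duration, vparams, seed = seeds[2L * i - 1L], rate = rate)
    ins <- gen_instruments(duration, iparams, seed = seeds[2L * i], rate = rate)
    p <- source_pair(v, ins, id = sprintf("track%02d", i))
    if (!is.null(rir)) render_scene(p, rir) else p
  })
  split <- chunk_and_split(tracks, fractions, chunk_s,
                           seed = seeds[2L * n_tracks + 1L])

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (part in c("train", "validation", "test")) {
      for (ch in split[[part]]) {
        base <- file.path(dir, ch$id)
        write_wav(ch$vocal, paste0(base, "_vocal.wav"), 32)
        write_wav(ch$instruments, paste0(base, "_instruments.wav"), 32)
        write_wav(ch$mixture, paste0(base, "_mixture.wav"), 32)
        files[[ch$id]] <- list(split = part, id = ch$id,
                               vocal = paste0(ch$id, "_vocal.wav"),
                               instruments = paste0(ch$id, "_instruments.wav"),
                               mixture = paste0(ch$id, "_mixture.wav"))
      }
    }
    manifest <- list(
      generator = "voxsep synthetic corpus",
      n_tracks = n_tracks, duration = duration, chunk_s = chunk_s,
      rate = rate, seed = seed, fractions = as.list(fractions),
      scene = if (!is.null(scene)) {
        list(t60 = scene$t60, direct_to_reverb_db = scene$direct_to_reverb_db,
             rir_s = scene$rir_s, metadata = scene$metadata)
      },
      vocal_params = unclass(vparams),
      instrument_params = unclass(iparams),
      tracks = unname(files)
    )
    mpath <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    attr(split, "manifest") <- mpath
  }
  split
}

#' Load a corpus written by [build_corpus()]
#'
#' @param dir Directory containing `manifest.json` and the chunk WAVs.
#' @return A `dataset_split` with the source pairs restored.
#' @export
load_corpus <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  out <- list(train = list(), validation = list(), test = list())
  for (tr in man$tracks) {
    p <- source_pair(read_wav(file.path(dir, tr$vocal)),
                     read_wav(file.path(dir, tr$instruments)),
                     id = tr$id)
    out[[tr$split]] <- c(out[[tr$split]], list(p))
  }
  structure(list(train = out$train, validation = out$validation,
                 test = out$test, assignment = NULL,
                 fractions = unlist(man$fractions), chunk_s = man$chunk_s,
                 seed = man$seed, manifest = man),
            class = "dataset_split")
}
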