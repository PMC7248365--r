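#' STFT analysis configuration
#'
#' Defaults follow the separator's front end: 1024-sample frames, 75%
#' overlap (hop of 256 samples) and a periodic Hamming window, giving
#' 513 one-sided frequency bins per frame.
#'
#' @param window_len Frame length in samples (even; default 1024).
#' @param hop Hop size in samples (default `window_len / 4`, i.e. 75%
#'   overlap).
#' @param window_kind Tapering function; only `"hamming"` (periodic) is
#'   implemented.
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(window_len = 1024, hop = window_len / 4,
                        window_kind = "hamming") {
  window_len <- as.integer(window_len)
  hop <- as.integer(hop)
  if (window_len <= 0L || window_len %% 2L != 0L) {
    stop("`window_len` must be a positive even integer")
  }
  if (hop <= 0L || hop > window_len) stop("need 0 < hop <= window_len")
  window_kind <- match.arg(window_kind, "hamming")
  n <- 0:(window_len - 1L)
  w <- 0.54 - 0.46 * cos(2 * pi * n / window_len)  # periodic Hamming
  structure(list(window_len = window_len, hop = hop,
                 window_kind = window_kind, window = w),
            class = "stft_config")
}

#' @export
print.stft_config <- function(x, ...) {
  cat(sprintf("<stft_config: window %d, hop %d (%.0f%% overlap), %s, %d bins>\n",
              x$window_len, x$hop, 100 * (1 - x$hop / x$window_len),
              x$window_kind, n_bins(x)))
  invisible(x)
}

#' Number of one-sided frequency bins per frame
#' @param cfg An [stft_config()].
#' @return `window_len / 2 + 1`.
#' @export
n_bins <- function(cfg) cfg$window_len %/% 2L + 1L

# Number of analysis frames for a signal of `len` samples: the signal is
# pre-padded with window_len - hop zeros and tail-padded so that every
# original sample is covered by the full window_len/hop overlapping frames.
num_frames <- function(len, cfg) {
  pre <- cfg$window_len - cfg$hop
  max(1L, as.integer(ceiling((pre + len) / cfg$hop)))
}

new_spectrogram <- function(z, cfg, origin_length, rate,
                            class = "spectrogram") {
  structure(list(z = z, cfg = cfg,
                 origin_length = as.integer(origin_length),
                 rate = rate),
            class = class)
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d bins x %d frames, origin %d samples @ %g Hz>\n",
              nrow(x$z), ncol(x$z), x$origin_length, x$rate))
  invisible(x)
}

#' @export
print.magnitude_spectrogram <- function(x, ...) {
  cat(sprintf("<magnitude_spectrogram: %d bins x %d frames, origin %d samples>\n",
              nrow(x$m), ncol(x$m), x$origin_length))
  invisible(x)
}

#' Short-time Fourier transform
#'
#' Analyzes a mono signal into overlapping windowed frames. The signal is
#' zero-padded with `window_len - hop` samples at the start and up to one
#' window at the end so that every input sample is covered by the full
#' complement of `window_len / hop` overlapping frames; this makes the
#' inverse transform an exact reconstruction (see [istft()]).
#'
#' @param x An [audio_signal()] (mono) or numeric vector.
#' @param cfg An [stft_config()].
#' @param rate Sampling rate, used only when `x` is a bare vector.
#' @return An object of class `spectrogram`: complex matrix `z`
#'   (`window_len/2 + 1` bins by frames) plus the analysis config,
#'   the original signal length and the sampling rate.
#' @export
stft <- function(x, cfg = stft_config(), rate = 44100) {
  x <- as_audio(x, rate)
  s <- x$samples
  if (!length(s)) stop("cannot analyze an empty signal")
  wl <- cfg$window_len
  hop <- cfg$hop
  nf <- num_frames(length(s), cfg)
  pre <- wl - hop
  padded_len <- (nf - 1L) * hop + wl
  padded <- numeric(padded_len)
  padded[pre + seq_along(s)] <- s
  idx <- outer(seq_len(wl), (seq_len(nf) - 1L) * hop, "+")
  frames <- matrix(padded[idx], nrow = wl) * cfg$window
  z <- stats::mvfft(frames)[seq_len(n_bins(cfg)), , drop = FALSE]
  new_spectrogram(z, cfg, length(s), x$rate)
}

#' Magnitude of a complex spectrogram
#'
#' @param spec A `spectrogram`.
#' @return An object of class `magnitude_spectrogram` with non-negative
#'   real matrix `m` of the same shape.
#' @export
magnitude <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  structure(list(m = abs(spec$z), cfg = spec$cfg,
                 origin_length = spec$origin_length, rate = spec$rate),
            class = "magnitude_spectrogram")
}

# Expand a one-sided spectrum matrix (bins x frames) to the full
# conjugate-symmetric window_len x frames matrix.
full_spectrum <- function(z, wl) {
  nb <- nrow(z)
  stopifnot(nb == wl %/% 2L + 1L)
  rbind(z, Conj(z[seq(nb - 1L, 2L), , drop = FALSE]))
}

# Sum of the shifted analysis windows over the padded timeline: the
# overlap-add normalizer. Strictly positive everywhere the original
# signal lives because of the edge padding.
ola_normalizer <- function(cfg, n_frames, padded_len) {
  norm <- numeric(padded_len)
  for (k in seq_len(n_frames)) {
    i <- (k - 1L) * cfg$hop + seq_len(cfg$window_len)
    norm[i] <- norm[i] + cfg$window
  }
  norm
}

#' Inverse STFT with overlap-add
#'
#' Inverts each frame, overlap-adds the windowed segments, divides by the
#' summed shifted analysis windows (constant-overlap-add normalization)
#' and trims to the original signal length. For any finite input,
#' `istft(stft(x))` reproduces `x` to floating-point accuracy.
#'
#' @param spec A `spectrogram` as produced by [stft()] (one-sided complex
#'   frames consistent with its config).
#' @return An [audio_signal()] of length `spec$origin_length`.
#' @export
istft <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  cfg <- spec$cfg
  wl <- cfg$window_len
  if (nrow(spec$z) != n_bins(cfg)) {
    stop("frame dimension ", nrow(spec$z), " inconsistent with config (",
         n_bins(cfg), " bins expected)")
  }
  nf <- ncol(spec$z)
  full <- full_spectrum(spec$z, wl)
  seg <- Re(stats::mvfft(full, inverse = TRUE)) / wl
  padded_len <- (nf - 1L) * cfg$hop + wl
  acc <- numeric(padded_len)
  for (k in seq_len(nf)) {
    i <- (k - 1L) * cfg$hop + seq_len(wl)
    acc[i] <- acc[i] + seg[, k]
  }
  norm <- ola_normalizer(cfg, nf, padded_len)
  pre <- wl - cfg$hop
  keep <- pre + seq_len(spec$origin_length)
  audio_signal(acc[keep] / norm[keep], spec$rate)
}

#' Resynthesize a magnitude spectrogram with the mixture phase
#'
#' Combines an estimated magnitude spectrum with the phase of the observed
#' mixture spectrum and inverts the result — the standard reconstruction
#' for magnitude-domain source separators.
#'
#' @param mag A `magnitude_spectrogram` (the estimate).
#' @param mixture_spec The mixture `spectrogram` supplying the phase; must
#'   have identical shape and analysis config.
#' @return An [audio_signal()].
#' @export
resynthesize_with_mixture_phase <- function(mag, mixture_spec) {
  stopifnot(inherits(mag, "magnitude_spectrogram"),
            inherits(mixture_spec, "spectrogram"))
  if (!identical(dim(mag$m), dim(mixture_spec$z))) {
    stop("magnitude and mixture spectrogram shapes differ")
  }
  if (mag$cfg$window_len != mixture_spec$cfg$window_len ||
      mag$cfg$hop != mixture_spec$cfg$hop) {
    stop("magnitude and mixture analysis configs differ")
  }
  z <- mag$m * exp(1i * Arg(mixture_spec$z))
  istft(new_spectrogram(z, mixture_spec$cfg, mixture_spec$origin_length,
                        mixture_spec$rate))
}

#' Algorithmic latency of the block-processing scheme
#'
#' The processing chain emits one hop of samples per analysis frame, so
#' its declared algorithmic latency is the hop duration. With the default
#' 1024-sample window, 25% hop and 44,100 Hz this is 5.805 ms, i.e. 6 ms
#' rounded. This is the latency *definition* used by the streaming engine
#' (one new hop must arrive before the next frame can be processed); the
#' additional overlap-add buffering delay is discussed in the package
#' vignette.
#'
#' @param cfg An [stft_config()].
#' @param rate Sampling rate in Hz.
#' @return A list with `ms` (exact, `hop / rate * 1000`) and `rounded`
#'   (nearest integer milliseconds).
#' @export
algorithmic_latency_ms <- function(cfg = stft_config(), rate = 44100) {
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be positive")
  ms <- cfg$hop / rate * 1000
  list(ms = ms, rounded = as.integer(round(ms)))
}
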