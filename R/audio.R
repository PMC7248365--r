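#' Mono audio signal container
#'
#' Light-weight container for a sampled audio waveform. The core processing
#' path is mono; stereo material read from WAV files is either downmixed
#' (mean of channels) or split per channel by [read_wav()].
#'
#' @param samples Numeric vector of amplitudes, nominally in `[-1, 1]`.
#'   All values must be finite (no `NA`/`NaN`/`Inf`).
#' @param rate Sampling rate in samples per second (default 44100).
#' @return An object of class `audio_signal`: a list with elements
#'   `samples` and `rate`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 440 * (0:999) / 44100))
#' duration_s(x)
#' @export
audio_signal <- function(samples, rate = 44100) {
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples))) {
    stop("audio signal contains non-finite samples (NaN/Inf)")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number")
  }
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), rms %.4g>\n",
              length(x$samples), x$rate, duration_s(x), signal_rms(x)))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

as_audio <- function(x, rate = 44100) {
  if (inherits(x, "audio_signal")) x else audio_signal(x, rate)
}

#' Signal duration in seconds
#' @param x An [audio_signal()].
#' @return Duration in seconds.
#' @export
duration_s <- function(x) {
  x <- as_audio(x)
  length(x$samples) / x$rate
}

#' Root-mean-square level of a signal
#'
#' @param x An [audio_signal()] or numeric vector.
#' @return The RMS amplitude (0 for an empty signal).
#' @export
signal_rms <- function(x) {
  s <- if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
  if (!length(s)) return(0)
  sqrt(mean(s^2))
}

stopifnot_same_rate <- function(a, b) {
  if (a$rate != b$rate) stop("sampling rates differ: ", a$rate, " vs ", b$rate)
}

# ---------------------------------------------------------------------------
# WAV I/O (RIFF/WAVE): PCM 16/24-bit and IEEE float32, little-endian.
# ---------------------------------------------------------------------------

#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader supporting 16- and 24-bit integer PCM and
#' 32-bit IEEE float, mono or stereo. Multi-channel material is downmixed
#' to mono (mean of channels) by default, matching the single-channel
#' processing path of the separator.
#'
#' @param path Path to a `.wav` file.
#' @param downmix If `TRUE` (default) average the channels to mono;
#'   if `FALSE`, return a list of one [audio_signal()] per channel.
#' @param expected_rate If non-`NULL`, error unless the file's sampling
#'   rate equals this value (resampling is out of scope).
#' @return An [audio_signal()] (or a list of them when `downmix = FALSE`
#'   and the file has several channels).
#' @export
read_wav <- function(path, downmix = TRUE, expected_rate = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1L, size = 2L, endian = "little", signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1L, size = 2L, endian = "little", signed = FALSE),
        rate = readBin(raw[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, size = 2L, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  if (!is.null(expected_rate) && fmt$rate != expected_rate) {
    stop("WAV rate ", fmt$rate, " != expected ", expected_rate,
         " (resampling not supported)")
  }

  x <- if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4L,
            endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
            endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
    v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    stop("unsupported WAV encoding: format ", fmt$format, ", ", fmt$bits, " bit")
  }

  nc <- fmt$channels
  if (nc == 1L) return(audio_signal(x, fmt$rate))
  m <- matrix(x, nrow = nc)
  if (downmix) {
    audio_signal(colMeans(m), fmt$rate)
  } else {
    lapply(seq_len(nc), function(i) audio_signal(m[i, ], fmt$rate))
  }
}

#' Write a WAV file
#'
#' @param x An [audio_signal()] (mono).
#' @param path Output path.
#' @param bit_depth One of 16, 24 (integer PCM) or 32 (IEEE float).
#'   Integer depths clip to `[-1, 1]` before quantization.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bit_depth = 16) {
  x <- as_audio(x)
  s <- x$samples
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(16L, 24L, 32L)) stop("bit_depth must be 16, 24 or 32")
  fmt_code <- if (bit_depth == 32L) 3L else 1L
  bytes_per <- bit_depth %/% 8L

  data_raw <- if (bit_depth == 32L) {
    writeBin(s, raw(), size = 4L, endian = "little")
  } else {
    full <- 2^(bit_depth - 1)
    q <- as.integer(round(pmax(pmin(s, 1), -1) * (full - 1)))
    if (bit_depth == 16L) {
      writeBin(q, raw(), size = 2L, endian = "little")
    } else {
      u <- ifelse(q < 0L, q + 16777216, q)
      rb <- rbind(u %% 256L, (u %/% 256L) %% 256L, (u %/% 65536L) %% 256L)
      as.raw(rb)
    }
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(data_raw)), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")            # channels
  writeBin(as.integer(x$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(x$rate) * bytes_per, con, size = 4L, endian = "little")
  writeBin(bytes_per, con, size = 2L, endian = "little")     # block align
  writeBin(bit_depth, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(data_raw)), con, size = 4L, endian = "little")
  writeBin(data_raw, con)
  invisible(path)
}
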