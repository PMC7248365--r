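#' Initialize a real-time separation/remix stream
#'
#' Creates the state for frame-by-frame processing: an input ring buffer
#' of one analysis window (primed with `window_len - hop` zeros, matching
#' the offline edge padding), the causal 3-frame context queue, and the
#' overlap-add accumulator. Feed audio with [push_block()] and drain the
#' tail with `flush()`; the concatenated output equals the offline
#' pipeline (separate + vocals-gain VIR remix) on the same signal.
#'
#' The declared algorithmic latency of the scheme is one hop
#' ([algorithmic_latency_ms()]): a frame can be processed as soon as one
#' new hop of input is available. The additional overlap-add buffering
#' delay is documented in the vignette.
#'
#' @param model A trained [separator_model()] or
#'   [passthrough_separator()].
#' @param cfg An [stft_config()] (bins must match the model).
#' @param rate Sampling rate (default 44100).
#' @param vir A [vir_setting()] applied in the spectral domain per frame.
#'   Balanced mode uses the two opposite gains without the offline
#'   final RMS renormalization (which needs the whole signal).
#' @return An environment of class `voxsep_stream`.
#' @export
stream_init <- function(model, cfg = stft_config(), rate = 44100,
                        vir = vir_setting(0, "vocals_gain")) {
  if (n_bins(cfg) != model$bins) stop("stft config bins != model bins")
  if (!isTRUE(model$trained)) stop("model is untrained")
  st <- new.env(parent = emptyenv())
  st$model <- model
  st$cfg <- cfg
  st$rate <- rate
  st$vir <- vir
  wl <- cfg$window_len; hop <- cfg$hop
  st$buf <- numeric(wl)                      # primed with the edge padding
  st$pending <- numeric(0)
  st$prev1 <- numeric(model$bins)
  st$prev2 <- numeric(model$bins)
  st$acc <- numeric(wl)                      # OLA accumulator
  # per-sample OLA normalizer profile of one emitted hop (full coverage)
  st$norm <- vapply(seq_len(hop),
                    function(r) sum(cfg$window[seq(r, wl, by = hop)]),
                    numeric(1))
  st$n_in <- 0L
  st$frames <- 0L
  st$emitted_padded <- 0L   # includes the discarded edge-padding region
  st$frame_ms <- numeric(0)
  st$flushed <- FALSE
  class(st) <- "voxsep_stream"
  st
}

#' @export
print.voxsep_stream <- function(x, ...) {
  cat(sprintf("<voxsep_stream: %d samples in, %d frames, vir %+d dB (%s)>\n",
              x$n_in, x$frames, x$vir$vir_db, x$vir$mode))
  invisible(x)
}

vir_gains <- function(vir) {
  if (vir$mode == "vocals_gain") {
    c(db_to_amp(vir$vir_db), 1)
  } else {
    c(10^(vir$vir_db / 40), 10^(-vir$vir_db / 40))
  }
}

# Process one frame sitting in st$buf; returns hop output samples on the
# padded timeline.
process_frame <- function(st) {
  t0 <- proc.time()[["elapsed"]]
  cfg <- st$cfg
  wl <- cfg$window_len; hop <- cfg$hop
  nb <- st$model$bins
  z <- stats::fft(st$buf * cfg$window)[seq_len(nb)]
  mag <- abs(z)

  feats <- structure(list(
    x = matrix(c(st$prev2, st$prev1, mag), nrow = 1L),
    bins = nb, cfg = cfg, origin_length = hop, rate = st$rate
  ), class = "context_features")
  preds <- forward(st$model, feats)
  vm <- preds$vocal$m[, 1L]
  im <- preds$instruments$m[, 1L]
  if (isTRUE(st$model$use_ratio_mask)) {
    r <- vm / (vm + im + 1e-12)
    vm <- r * mag
    im <- (1 - r) * mag
  }
  st$prev2 <- st$prev1
  st$prev1 <- mag

  g <- vir_gains(st$vir)
  phase <- exp(1i * Arg(z))
  zm <- (g[1] * vm + g[2] * im) * phase
  full <- c(zm, Conj(zm[seq(nb - 1L, 2L)]))
  seg <- Re(stats::fft(full, inverse = TRUE)) / wl

  st$acc <- st$acc + seg
  chunk <- st$acc[seq_len(hop)] / st$norm
  st$acc <- c(st$acc[(hop + 1L):wl], numeric(hop))
  st$frames <- st$frames + 1L
  st$frame_ms <- c(st$frame_ms, (proc.time()[["elapsed"]] - t0) * 1000)
  chunk
}

# Drop the part of an emitted padded-timeline chunk that belongs to the
# edge padding (the first window_len - hop samples).
trim_padding <- function(st, chunk) {
  pre <- st$cfg$window_len - st$cfg$hop
  drop <- max(0L, min(length(chunk), pre - st$emitted_padded))
  st$emitted_padded <- st$emitted_padded + length(chunk)
  if (drop) chunk[-seq_len(drop)] else chunk
}

#' Push an audio block through the stream
#'
#' Consumes a block of arbitrary size; whenever one hop of new samples is
#' available, one frame is analyzed, separated, remixed and overlap-added,
#' emitting exactly `hop` output samples per completed frame. The VIR may
#' be changed between blocks; a new setting takes effect from the next
#' synthesized frame (no cross-fade).
#'
#' @param st A `voxsep_stream` from [stream_init()].
#' @param samples Numeric vector or [audio_signal()] (rate must match).
#' @param vir Optional [vir_setting()] replacing the current one.
#' @return Numeric vector of newly emitted output samples (possibly
#'   empty).
#' @export
push_block <- function(st, samples, vir = NULL) {
  stopifnot(inherits(st, "voxsep_stream"))
  if (st$flushed) stop("stream already flushed")
  if (inherits(samples, "audio_signal")) {
    if (samples$rate != st$rate) stop("sample-rate mismatch")
    samples <- samples$samples
  }
  if (!is.null(vir)) {
    stopifnot(inherits(vir, "vir_setting"))
    st$vir <- vir
  }
  st$pending <- c(st$pending, as.numeric(samples))
  st$n_in <- st$n_in + length(samples)
  hop <- st$cfg$hop
  out <- list()
  while (length(st$pending) >= hop) {
    new <- st$pending[seq_len(hop)]
    st$pending <- st$pending[-seq_len(hop)]
    st$buf <- c(st$buf[-seq_len(hop)], new)
    out[[length(out) + 1L]] <- trim_padding(st, process_frame(st))
  }
  unlist(out, use.names = FALSE)
}

#' Drain the overlap-add tail of a stream
#'
#' Feeds zeros until every input sample has been synthesized and emitted,
#' so that the total output length equals the total input length.
#' Idempotent: a second call returns an empty vector.
#'
#' @param con A `voxsep_stream`.
#' @param ... Unused.
#' @return Numeric vector of trailing output samples.
#' @export
#' @method flush voxsep_stream
flush.voxsep_stream <- function(con, ...) {
  st <- con
  if (st$flushed) return(numeric(0))
  st$flushed <- TRUE
  if (st$n_in == 0L) return(numeric(0))
  cfg <- st$cfg
  hop <- cfg$hop
  pre <- cfg$window_len - hop
  total_frames <- as.integer(ceiling((pre + st$n_in) / hop))
  already_emitted <- max(0L, st$frames * hop - pre)
  out <- list()
  while (st$frames < total_frames) {
    pad <- hop - length(st$pending)
    st$buf <- c(st$buf[-seq_len(hop)], st$pending, numeric(pad))
    st$pending <- numeric(0)
    out[[length(out) + 1L]] <- trim_padding(st, process_frame(st))
  }
  out <- unlist(out, use.names = FALSE)
  keep <- st$n_in - already_emitted
  out[seq_len(min(keep, length(out)))]
}

#' Latency and throughput report of a stream
#'
#' The algorithmic latency is the hop duration — the declared contract of
#' the block-processing scheme. Per-frame processing times are logged
#' (wall clock) and summarized; they are hardware-dependent and reported
#' for information only.
#'
#' @param st A `voxsep_stream`.
#' @return A list: `algorithmic_ms`, `algorithmic_ms_rounded`,
#'   `frames_processed`, `emitted_samples`, `mean_frame_ms`,
#'   `max_frame_ms`, `real_time_factor` (mean processing time per frame
#'   over the hop duration; < 1 means faster than real time).
#' @export
stream_latency_report <- function(st) {
  stopifnot(inherits(st, "voxsep_stream"))
  lat <- algorithmic_latency_ms(st$cfg, st$rate)
  mean_ms <- if (length(st$frame_ms)) mean(st$frame_ms) else NA_real_
  list(algorithmic_ms = lat$ms,
       algorithmic_ms_rounded = lat$rounded,
       frames_processed = st$frames,
       emitted_samples = max(0L, st$emitted_padded -
                               (st$cfg$window_len - st$cfg$hop)),
       mean_frame_ms = mean_ms,
       max_frame_ms = if (length(st$frame_ms)) max(st$frame_ms) else NA_real_,
       real_time_factor = mean_ms / lat$ms)
}
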