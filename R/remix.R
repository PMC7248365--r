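#' Vocals-to-instruments ratio (VIR) remix setting
#'
#' The VIR is the power ratio of the vocal to the instruments signal in
#' dB. The user control is a 25-position slider on a 1-dB grid from -12
#' to +12 dB. Two adjustment modes are provided:
#'
#' * `vocals_gain` — the instruments level stays fixed and the vocals are
#'   scaled by `vir_db` dB (the overall level varies with the setting);
#' * `balanced` — the vocals and instruments are moved in opposite
#'   directions by `vir_db / 2` dB each and the mix is then renormalized
#'   so its RMS equals `reference_rms` exactly (constant presentation
#'   level, the digital stand-in for a 65 dB SPL calibration).
#'
#' @param vir_db Integer dB in `[-12, 12]`.
#' @param mode `"vocals_gain"` or `"balanced"`.
#' @param reference_rms Digital RMS corresponding to the calibrated
#'   presentation level (default 0.05 full scale).
#' @return An object of class `vir_setting`.
#' @export
vir_setting <- function(vir_db = 0, mode = c("vocals_gain", "balanced"),
                        reference_rms = 0.05) {
  mode <- match.arg(mode)
  if (!is.numeric(vir_db) || length(vir_db) != 1L || !is.finite(vir_db) ||
      vir_db != round(vir_db) || vir_db < -12 || vir_db > 12) {
    stop("`vir_db` must be an integer in [-12, 12]")
  }
  if (!is.numeric(reference_rms) || reference_rms <= 0) {
    stop("`reference_rms` must be positive")
  }
  structure(list(vir_db = as.integer(vir_db), mode = mode,
                 reference_rms = reference_rms),
            class = "vir_setting")
}

#' Quantize a raw dB value onto the VIR slider grid
#'
#' Nearest 1-dB grid position, clipped to `[-12, 12]`; half-way values
#' round away from zero.
#'
#' @param raw_db Real dB value.
#' @return Integer dB on the slider grid.
#' @export
quantize_vir <- function(raw_db) {
  if (!is.numeric(raw_db) || length(raw_db) != 1L || is.nan(raw_db)) {
    stop("`raw_db` must be a single non-NaN number")
  }
  q <- sign(raw_db) * floor(abs(raw_db) + 0.5)
  as.integer(max(-12, min(12, q)))
}

#' Remix vocal and instruments estimates at a chosen VIR
#'
#' @param vocal,instruments [audio_signal()]s of equal length and rate
#'   (typically the outputs of [separate()]).
#' @param setting A [vir_setting()].
#' @return The remixed [audio_signal()] `m(t)`. In `vocals_gain` mode
#'   `m = 10^(vir/20) * v + i`; in `balanced` mode
#'   `m' = 10^(vir/40) * v + 10^(-vir/40) * i` rescaled so
#'   `rms(m) == reference_rms` exactly.
#' @export
apply_vir <- function(vocal, instruments, setting = vir_setting()) {
  vocal <- as_audio(vocal); instruments <- as_audio(instruments)
  stopifnot_same_rate(vocal, instruments)
  if (length(vocal$samples) != length(instruments$samples)) {
    stop("vocal and instruments lengths differ")
  }
  stopifnot(inherits(setting, "vir_setting"))
  v <- vocal$samples; i <- instruments$samples
  if (setting$mode == "vocals_gain") {
    m <- db_to_amp(setting$vir_db) * v + i
  } else {
    m <- 10^(setting$vir_db / 40) * v + 10^(-setting$vir_db / 40) * i
    r <- sqrt(mean(m^2))
    if (r == 0) stop("balanced remix is silent; cannot normalize level")
    m <- m * (setting$reference_rms / r)
  }
  audio_signal(m, vocal$rate)
}

#' Calibrate a signal to a reference RMS level
#'
#' Scales the signal so its RMS equals `reference_rms` exactly — the
#' digital counterpart of presenting material at a fixed sound pressure
#' level.
#'
#' @param x An [audio_signal()].
#' @param reference_rms Target RMS (> 0).
#' @return The scaled [audio_signal()].
#' @export
calibrate_level <- function(x, reference_rms = 0.05) {
  x <- as_audio(x)
  r <- signal_rms(x)
  if (r == 0) stop("cannot calibrate a silent signal")
  if (reference_rms <= 0) stop("`reference_rms` must be positive")
  audio_signal(x$samples * (reference_rms / r), x$rate)
}
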