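#' Time-aligned vocal/instruments source pair
#'
#' The unit of training and evaluation data: a vocal signal, an
#' instruments signal and their mixture `x(t) = y1(t) + y2(t)`.
#'
#' @param vocal,instruments [audio_signal()]s of equal length and rate.
#' @param mixture Optional mixture signal; computed as the sample-wise sum
#'   when omitted. When supplied it must equal `vocal + instruments`
#'   within `1e-9` unless `validate = FALSE` (used for *estimated* pairs,
#'   where the estimates need not sum to the observed mixture).
#' @param id Identifier string.
#' @param validate Check the mixture-sum invariant (default `TRUE`).
#' @return An object of class `source_pair`.
#' @export
source_pair <- function(vocal, instruments, mixture = NULL,
                        id = "pair", validate = TRUE) {
  vocal <- as_audio(vocal); instruments <- as_audio(instruments)
  stopifnot_same_rate(vocal, instruments)
  if (length(vocal$samples) != length(instruments$samples)) {
    stop("vocal and instruments lengths differ")
  }
  if (is.null(mixture)) {
    mixture <- audio_signal(vocal$samples + instruments$samples, vocal$rate)
  } else {
    mixture <- as_audio(mixture)
    stopifnot_same_rate(vocal, mixture)
    if (length(mixture$samples) != length(vocal$samples)) {
      stop("mixture length differs from sources")
    }
    if (validate) {
      dev <- max(abs(mixture$samples - vocal$samples - instruments$samples), 0)
      if (dev > 1e-9) {
        stop("mixture != vocal + instruments (max deviation ", signif(dev, 3), ")")
      }
    }
  }
  structure(list(vocal = vocal, instruments = instruments,
                 mixture = mixture, id = as.character(id)),
            class = "source_pair")
}

#' @export
print.source_pair <- function(x, ...) {
  cat(sprintf("<source_pair '%s': %.2f s @ %g Hz>\n",
              x$id, duration_s(x$mixture), x$mixture$rate))
  invisible(x)
}

chunk_track <- function(pair, chunk_s) {
  n <- length(pair$mixture$samples)
  rate <- pair$mixture$rate
  chunk_n <- as.integer(round(chunk_s * rate))
  if (n <= chunk_n) return(list(pair))
  k <- n %/% chunk_n  # final shorter remainder is dropped
  lapply(seq_len(k), function(i) {
    idx <- (i - 1L) * chunk_n + seq_len(chunk_n)
    source_pair(audio_signal(pair$vocal$samples[idx], rate),
                audio_signal(pair$instruments$samples[idx], rate),
                id = sprintf("%s_c%02d", pair$id, i))
  })
}

#' Chunk tracks and split them into train/validation/test sets
#'
#' Tracks longer than the chunk length are cut into consecutive fixed-
#' length chunks (a final shorter remainder is dropped). Whole tracks —
#' never individual chunks — are assigned to the three sets, so no track
#' spans two splits. Set sizes follow the fractions via largest-remainder
#' rounding; assignment order is randomized by the seed.
#'
#' @param tracks List of [source_pair()]s.
#' @param fractions Named numeric vector `c(train=, validation=, test=)`
#'   summing to 1 (default `0.6/0.2/0.2`).
#' @param chunk_s Chunk length in seconds (default 30).
#' @param seed Integer seed controlling the randomized assignment.
#' @return An object of class `dataset_split`: lists `train`,
#'   `validation`, `test` of source-pair chunks, plus an `assignment`
#'   data frame (track id, split) and the call parameters.
#' @export
chunk_and_split <- function(tracks,
                            fractions = c(train = 0.6, validation = 0.2,
                                          test = 0.2),
                            chunk_s = 30, seed = 1) {
  if (!length(tracks)) stop("`tracks` must be non-empty")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be three values summing to 1")
  }
  names(fractions) <- c("train", "validation", "test")
  n <- length(tracks)

  # largest-remainder apportionment of n tracks to the three sets
  raw <- fractions * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }

  perm <- with_seed(seed, sample.int(n))
  split_of <- rep(names(fractions), times = counts)
  assignment <- data.frame(
    id = vapply(tracks, function(p) p$id, character(1))[perm],
    split = split_of, stringsAsFactors = FALSE
  )

  out <- list(train = list(), validation = list(), test = list())
  for (j in seq_len(n)) {
    tr <- tracks[[perm[j]]]
    out[[split_of[j]]] <- c(out[[split_of[j]]], chunk_track(tr, chunk_s))
  }
  structure(list(train = out$train, validation = out$validation,
                 test = out$test, assignment = assignment,
                 fractions = fractions, chunk_s = chunk_s, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: %d/%d/%d train/validation/test chunks (%g s)>\n",
              length(x$train), length(x$validation), length(x$test),
              x$chunk_s))
  invisible(x)
}
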