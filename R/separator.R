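#' Stack causal context frames into network input features
#'
#' The separator looks at three consecutive magnitude frames with two
#' frames of overlap between successive inputs: row `t` of the feature
#' matrix is the concatenation `[frame(t-2), frame(t-1), frame(t)]`, with
#' zero vectors in place of frames before the start of the signal. The
#' context is causal — no lookahead — so it adds nothing to the
#' algorithmic latency.
#'
#' @param mag A `magnitude_spectrogram` (see [magnitude()]).
#' @return An object of class `context_features`: matrix `x` of shape
#'   (frames x 3*bins) plus the analysis metadata needed to rebuild
#'   spectrograms from per-frame predictions.
#' @export
stack_context <- function(mag) {
  stopifnot(inherits(mag, "magnitude_spectrogram"))
  m <- mag$m
  nf <- ncol(m)
  if (!nf) stop("empty spectrogram")
  nb <- nrow(m)
  tm <- t(m)
  zero <- function(k) matrix(0, nrow = k, ncol = nb)
  lag2 <- if (nf > 2L) rbind(zero(2L), tm[seq_len(nf - 2L), , drop = FALSE]) else zero(nf)
  lag1 <- if (nf > 1L) rbind(zero(1L), tm[seq_len(nf - 1L), , drop = FALSE]) else zero(nf)
  structure(list(x = cbind(lag2, lag1, tm), bins = nb, cfg = mag$cfg,
                 origin_length = mag$origin_length, rate = mag$rate),
            class = "context_features")
}

#' Separator network definition
#'
#' A three-layer perceptron mapping a 3-frame magnitude context
#' (`3 * bins` inputs, 1539 with the default STFT) through one hidden
#' rectified-linear layer to `2 * bins` outputs (1026 by default): the
#' first half is the vocal magnitude spectrum, the second half the
#' instruments spectrum. A rectifier at the output keeps predicted
#' magnitudes non-negative. The feature-scaling constant (learned from the
#' training data by [train_separator()]) is stored with the weights.
#'
#' @param bins Spectral bins per frame (default 513).
#' @param hidden Hidden-layer width (default 1024).
#' @param context Number of stacked input frames (fixed at 3).
#' @param seed Seed for the random weight initialization (He-scaled
#'   Gaussians; biases start at zero).
#' @param use_ratio_mask If `TRUE`, [separate()] converts the two output
#'   spectra into a ratio mask `v/(v + i + eps)` applied to the mixture
#'   magnitude instead of using them directly.
#' @return An object of class `separator_model`.
#' @export
separator_model <- function(bins = 513, hidden = 1024, context = 3,
                            seed = 1, use_ratio_mask = FALSE) {
  bins <- as.integer(bins); hidden <- as.integer(hidden)
  input_dim <- context * bins
  output_dim <- 2L * bins
  pars <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(input_dim * hidden, sd = sqrt(2 / input_dim)),
                input_dim, hidden),
    W2 = matrix(stats::rnorm(hidden * output_dim, sd = sqrt(2 / hidden)),
                hidden, output_dim)
  ))
  structure(list(W1 = pars$W1, b1 = numeric(hidden),
                 W2 = pars$W2, b2 = numeric(output_dim),
                 bins = bins, hidden = hidden, context = as.integer(context),
                 scale = 1, use_ratio_mask = isTRUE(use_ratio_mask),
                 seed = seed, trained = FALSE, version = "voxsep-model-1"),
            class = "separator_model")
}

#' @export
print.separator_model <- function(x, ...) {
  cat(sprintf(
    "<separator_model: %d -> %d -> %d (%strained, scale %.4g)>\n",
    x$context * x$bins, x$hidden, 2L * x$bins,
    if (isTRUE(x$trained)) "" else "un", x$scale))
  invisible(x)
}

#' Training configuration for the separator
#'
#' Defaults are the published recipe: mini-batches of 128 frame rows,
#' Adam with an initial learning rate of 0.005 multiplied by 0.9 after
#' every epoch, 100 epochs, and dropout with probability 0.8 on the
#' hidden layer (training only, inverted scaling). The loss is the mean
#' squared error on (scaled) linear magnitude spectra over both source
#' halves jointly.
#'
#' @param batch_size Frames per mini-batch (default 128).
#' @param lr Initial learning rate (default 0.005).
#' @param lr_decay Multiplicative learning-rate decay applied after each
#'   epoch (default 0.9).
#' @param epochs Number of training epochs (default 100).
#' @param dropout Dropout probability on the hidden layer (default 0.8).
#' @param dropout_is_keep_prob Interpret `dropout` as the *keep*
#'   probability instead of the drop probability (default `FALSE`).
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 128, lr = 0.005, lr_decay = 0.9,
                         epochs = 100, dropout = 0.8,
                         dropout_is_keep_prob = FALSE, seed = 1,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  stopifnot(batch_size >= 1, epochs >= 1, dropout >= 0, dropout < 1,
            lr > 0, lr_decay > 0)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 lr_decay = lr_decay, epochs = as.integer(epochs),
                 dropout = dropout,
                 dropout_is_keep_prob = isTRUE(dropout_is_keep_prob),
                 seed = seed, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps),
            class = "train_config")
}

relu <- function(x) (x > 0) * x

# Raw two-layer forward pass on an already-scaled feature matrix.
mlp_forward_scaled <- function(model, xs) {
  h <- relu(sweep(xs %*% model$W1, 2L, model$b1, "+", check.margin = FALSE))
  relu(sweep(h %*% model$W2, 2L, model$b2, "+", check.margin = FALSE))
}

check_model_finite <- function(model) {
  if (!all(is.finite(model$W1)) || !all(is.finite(model$W2)) ||
      !all(is.finite(model$b1)) || !all(is.finite(model$b2)) ||
      !is.finite(model$scale) || model$scale <= 0) {
    stop("separator model has non-finite parameters or invalid scale")
  }
}

#' Run the separator network on context features
#'
#' Inference pass (dropout inactive). Outputs are non-negative by
#' construction; the first half of each output row is the vocal spectrum,
#' the second half the instruments spectrum.
#'
#' @param model A [separator_model()] (or [passthrough_separator()]).
#' @param feats `context_features` from [stack_context()].
#' @return A list with `vocal` and `instruments`, both
#'   `magnitude_spectrogram`s with `bins` rows each.
#' @export
forward <- function(model, feats) {
  UseMethod("forward")
}

#' @export
forward.separator_model <- function(model, feats) {
  stopifnot(inherits(feats, "context_features"))
  if (ncol(feats$x) != model$context * model$bins) {
    stop("feature dimension ", ncol(feats$x), " != model input dim ",
         model$context * model$bins)
  }
  check_model_finite(model)
  y <- mlp_forward_scaled(model, feats$x / model$scale) * model$scale
  nb <- model$bins
  wrap <- function(m) {
    structure(list(m = m, cfg = feats$cfg,
                   origin_length = feats$origin_length, rate = feats$rate),
              class = "magnitude_spectrogram")
  }
  list(vocal = wrap(t(y[, seq_len(nb), drop = FALSE])),
       instruments = wrap(t(y[, nb + seq_len(nb), drop = FALSE])))
}

#' Pass-through separator stub
#'
#' A degenerate "separator" that declares the whole mixture to be vocals
#' and silence to be instruments. Useful as an identity element for
#' latency tracking and pipeline plumbing tests: with a 0 dB
#' vocals-gain remix the full chain reproduces its input.
#'
#' @param bins Spectral bins per frame (default 513).
#' @return An object of classes `passthrough_separator`, `separator_model`.
#' @export
passthrough_separator <- function(bins = 513) {
  structure(list(bins = as.integer(bins), hidden = 0L, context = 3L,
                 scale = 1, use_ratio_mask = FALSE, trained = TRUE,
                 version = "voxsep-model-1"),
            class = c("passthrough_separator", "separator_model"))
}

#' @export
forward.passthrough_separator <- function(model, feats) {
  stopifnot(inherits(feats, "context_features"))
  nb <- model$bins
  if (feats$bins != nb) stop("bin count mismatch")
  cur <- feats$x[, 2L * nb + seq_len(nb), drop = FALSE]
  wrap <- function(m) {
    structure(list(m = m, cfg = feats$cfg,
                   origin_length = feats$origin_length, rate = feats$rate),
              class = "magnitude_spectrogram")
  }
  list(vocal = wrap(t(cur)),
       instruments = wrap(matrix(0, nb, nrow(feats$x))))
}

# Pool STFT features and magnitude targets over a list of source pairs.
build_training_matrices <- function(pairs, stft_cfg) {
  xs <- vector("list", length(pairs))
  ts <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    mix_spec <- stft(p$mixture, stft_cfg)
    xs[[i]] <- stack_context(magnitude(mix_spec))$x
    ts[[i]] <- cbind(t(abs(stft(p$vocal, stft_cfg)$z)),
                     t(abs(stft(p$instruments, stft_cfg)$z)))
  }
  list(x = do.call(rbind, xs), t = do.call(rbind, ts))
}

#' Train the separator network
#'
#' Minimizes the mean squared error between predicted and true magnitude
#' spectra of both sources jointly, with mini-batch Adam. Frame rows from
#' all training chunks are pooled and reshuffled each epoch; the learning
#' rate is multiplied by `lr_decay` after every epoch; dropout is applied
#' to the hidden layer during training only. Input and target magnitudes
#' are divided by a single scalar — the training set's 99th-percentile
#' mixture magnitude — which is stored in the returned model and reapplied
#' at inference.
#'
#' @param pairs Non-empty list of [source_pair()]s (training chunks).
#' @param cfg A [train_config()].
#' @param stft_cfg An [stft_config()].
#' @param hidden Hidden-layer width (default 1024).
#' @param use_ratio_mask Passed to [separator_model()].
#' @param validation Optional list of [source_pair()]s; when supplied, a
#'   (dropout-free) validation loss is recorded per epoch.
#' @param verbose Print per-epoch progress.
#' @return A list with `model` (trained [separator_model()]) and
#'   `history` (data frame: epoch, lr, loss, and validation_loss if
#'   requested; one row per epoch).
#' @export
train_separator <- function(pairs, cfg = train_config(),
                            stft_cfg = stft_config(), hidden = 1024,
                            use_ratio_mask = FALSE, validation = NULL,
                            verbose = FALSE) {
  if (!length(pairs)) stop("`pairs` must be non-empty")
  dat <- build_training_matrices(pairs, stft_cfg)
  bins <- n_bins(stft_cfg)
  scale <- as.numeric(stats::quantile(dat$x[, 2L * bins + seq_len(bins)],
                                      0.99, names = FALSE))
  if (scale <= 0) scale <- 1
  dat$x <- dat$x / scale
  dat$t <- dat$t / scale
  X <- dat$x
  Tg <- dat$t
  val <- if (!is.null(validation)) {
    v <- build_training_matrices(validation, stft_cfg)
    list(x = v$x / scale, t = v$t / scale)
  }

  model <- separator_model(bins = bins, hidden = hidden, seed = cfg$seed,
                           use_ratio_mask = use_ratio_mask)
  model$scale <- scale
  drop_p <- if (cfg$dropout_is_keep_prob) 1 - cfg$dropout else cfg$dropout
  keep_p <- 1 - drop_p
  n <- nrow(X)
  bs <- min(cfg$batch_size, n)

  # Adam state. The parameter, moment and velocity buffers are updated in
  # place by the C kernel, so each must be a freshly allocated array that
  # nothing else references.
  params <- list(W1 = model$W1 + 0, b1 = model$b1 + 0,
                 W2 = model$W2 + 0, b2 = model$b2 + 0)
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  step <- 0L
  lr <- cfg$lr
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2; eps <- cfg$adam_eps

  history <- data.frame(epoch = seq_len(cfg$epochs), lr = NA_real_,
                        loss = NA_real_)
  if (!is.null(val)) history$validation_loss <- NA_real_

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    epoch_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + bs - 1L, n)]
      xb <- X[idx, , drop = FALSE]
      tb <- Tg[idx, , drop = FALSE]
      nb_rows <- length(idx)

      z1 <- sweep(xb %*% params$W1, 2L, params$b1, "+", check.margin = FALSE)
      h <- relu(z1)
      if (drop_p > 0) {
        mask <- (stats::runif(length(h)) >= drop_p) / keep_p
        dim(mask) <- dim(h)
        h <- h * mask
      }
      z2 <- sweep(h %*% params$W2, 2L, params$b2, "+", check.margin = FALSE)
      y <- relu(z2)

      err <- y - tb
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop(sprintf(
          "training diverged: non-finite loss at epoch %d (lr %.4g); %s",
          epoch, lr, "reduce the learning rate or check the input data"))
      }
      epoch_loss <- epoch_loss + loss * nb_rows

      dz2 <- err * (z2 > 0) * (2 / length(err))
      gW2 <- crossprod(h, dz2)
      gb2 <- colSums(dz2)
      dh <- tcrossprod(dz2, params$W2)
      if (drop_p > 0) dh <- dh * mask
      dz1 <- dh * (z1 > 0)
      gW1 <- crossprod(xb, dz1)
      gb1 <- colSums(dz1)

      step <- step + 1L
      corr1 <- 1 - b1^step
      corr2 <- 1 - b2^step
      for (nm in c("W1", "b1", "W2", "b2")) {
        g <- switch(nm, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        .Call(voxsep_adam_step, params[[nm]], g, mom[[nm]], vel[[nm]],
              lr, b1, b2, eps, corr1, corr2)
      }
    }
    history$lr[epoch] <- lr
    history$loss[epoch] <- epoch_loss / n
    if (!is.null(val)) {
      model[c("W1", "b1", "W2", "b2")] <- params
      pv <- mlp_forward_scaled(model, val$x)
      history$validation_loss[epoch] <- mean((pv - val$t)^2)
    }
    if (verbose) {
      message(sprintf("epoch %3d  lr %.5f  loss %.6g", epoch, lr,
                      history$loss[epoch]))
    }
    lr <- lr * cfg$lr_decay
  }
  model[c("W1", "b1", "W2", "b2")] <- params
  model$trained <- TRUE
  model$train_config <- cfg
  model$stft <- list(window_len = stft_cfg$window_len, hop = stft_cfg$hop,
                     window_kind = stft_cfg$window_kind)
  list(model = model, history = history)
}

#' Separate a mixture into vocal and instruments estimates
#'
#' Full inference pipeline: STFT, magnitude, feature scaling, causal
#' context stacking, network forward pass, and per-source resynthesis
#' with the mixture phase. Estimates have exactly the length of the
#' input mixture.
#'
#' @param model A trained [separator_model()] (or
#'   [passthrough_separator()]).
#' @param mixture The mixture [audio_signal()].
#' @param stft_cfg An [stft_config()] compatible with the model's bin
#'   count.
#' @return A [source_pair()] of *estimated* vocal and instruments (its
#'   `mixture` field is the input mixture; estimates need not sum to it).
#' @export
separate <- function(model, mixture, stft_cfg = stft_config()) {
  mixture <- as_audio(mixture)
  if (n_bins(stft_cfg) != model$bins) {
    stop("stft config bins (", n_bins(stft_cfg),
         ") != model bins (", model$bins, ")")
  }
  if (!isTRUE(model$trained)) stop("model is untrained; run train_separator()")
  check_model_finite(model)
  spec <- stft(mixture, stft_cfg)
  mag <- magnitude(spec)
  preds <- forward(model, stack_context(mag))
  vmag <- preds$vocal; imag <- preds$instruments
  if (isTRUE(model$use_ratio_mask)) {
    eps <- 1e-12
    vm <- vmag$m / (vmag$m + imag$m + eps)
    vmag$m <- vm * mag$m
    imag$m <- (1 - vm) * mag$m
  }
  est_v <- resynthesize_with_mixture_phase(vmag, spec)
  est_i <- resynthesize_with_mixture_phase(imag, spec)
  source_pair(est_v, est_i, mixture = mixture, id = "estimate",
              validate = FALSE)
}

#' Save / load a separator checkpoint
#'
#' The checkpoint is a plain, versioned R list (tag `voxsep-model-1`)
#' holding the weight matrices, biases, feature-scaling constant, STFT
#' configuration, training configuration and seed, serialized with
#' [saveRDS()]. [load_separator()] validates the version tag.
#'
#' @param model A [separator_model()].
#' @param path File path for the checkpoint.
#' @return `path` (save) or the restored model (load), invisibly/visibly.
#' @export
save_separator <- function(model, path) {
  stopifnot(inherits(model, "separator_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_separator
#' @export
load_separator <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, "voxsep-model-1")) {
    stop("unrecognized checkpoint version: ", obj$version)
  }
  cls <- if (identical(obj$hidden, 0L)) {
    c("passthrough_separator", "separator_model")
  } else "separator_model"
  structure(obj, class = cls)
}

#' Oracle (ideal-magnitude) separation
#'
#' Reconstructs each source from its *true* magnitude spectrogram
#' combined with the mixture phase — the upper bound attainable by any
#' magnitude-domain separator under mixture-phase resynthesis. Used as a
#' reference in capacity and benchmark tests.
#'
#' @param pair A ground-truth [source_pair()].
#' @param stft_cfg An [stft_config()].
#' @return A [source_pair()] of oracle estimates.
#' @export
ideal_magnitude_separation <- function(pair, stft_cfg = stft_config()) {
  stopifnot(inherits(pair, "source_pair"))
  mix_spec <- stft(pair$mixture, stft_cfg)
  est_v <- resynthesize_with_mixture_phase(
    magnitude(stft(pair$vocal, stft_cfg)), mix_spec)
  est_i <- resynthesize_with_mixture_phase(
    magnitude(stft(pair$instruments, stft_cfg)), mix_spec)
  source_pair(est_v, est_i, mixture = pair$mixture, id = "oracle",
              validate = FALSE)
}
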