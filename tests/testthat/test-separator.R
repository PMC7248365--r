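# Context stacking, the MLP, training recipe, and dataset splitting.

test_that("context stacking is causal with zero padding and 3x bin width", {
  mag <- magnitude(stft(random_signal(2000), small_cfg()))
  feats <- stack_context(mag)
  nb <- n_bins(small_cfg())
  expect_equal(ncol(feats$x), 3L * nb)
  expect_equal(nrow(feats$x), ncol(mag$m))
  # default config gives the published 513*3 input width
  expect_equal(ncol(stack_context(magnitude(stft(
    random_signal(4000, rate = 44100), stft_config())))$x), 1539L)

  # single frame: [0, 0, frame0]
  one <- mag; one$m <- mag$m[, 1, drop = FALSE]
  f1 <- stack_context(one)
  expect_equal(nrow(f1$x), 1L)
  expect_true(all(f1$x[1, seq_len(2 * nb)] == 0))
  expect_equal(f1$x[1, 2 * nb + seq_len(nb)], mag$m[, 1])

  # 5-frame spectrogram with frame i constant i+1: row 3 = [2,3,4] blockwise
  five <- mag
  five$m <- matrix(rep(2:6, each = nb), nrow = nb)
  r3 <- stack_context(five)$x[3, ]
  expect_equal(unname(r3), rep(c(2, 3, 4), each = nb))
  empty <- mag; empty$m <- mag$m[, 0, drop = FALSE]
  expect_error(stack_context(empty), "empty")
})

test_that("forward pass dimensions, zero model, and non-negativity", {
  cfg <- small_cfg()
  nb <- n_bins(cfg)
  feats <- stack_context(magnitude(stft(random_signal(1000, seed = 3), cfg)))
  m <- random_model(nb, hidden = 8, seed = 4)
  out <- forward(m, feats)
  expect_equal(nrow(out$vocal$m), nb)
  expect_equal(nrow(out$instruments$m), nb)
  expect_equal(ncol(out$vocal$m), nrow(feats$x))
  expect_true(all(out$vocal$m >= 0))
  expect_true(all(out$instruments$m >= 0))

  z <- m; z$W1[] <- 0; z$W2[] <- 0
  outz <- forward(z, feats)
  expect_true(all(outz$vocal$m == 0) && all(outz$instruments$m == 0))

  # published output width: 2 * 513 = 1026 units
  big <- separator_model()
  expect_equal(ncol(big$W2), 1026L)
  expect_equal(nrow(big$W1), 1539L)
  wrong <- feats; wrong$x <- wrong$x[, -1, drop = FALSE]
  expect_error(forward(m, wrong), "dimension")
})

test_that("hand-built 1-bin toy network matches the rectified affine map", {
  # bins = 1, context 3, hidden 2: y = relu(W2' relu(W1' x + b1) + b2)
  m <- separator_model(bins = 1, hidden = 2, context = 3, seed = 1)
  m$W1 <- matrix(c(1, 0, 0,
                   -1, 1, 0), nrow = 3)   # h1 = x1, h2 = x2 - x1
  m$b1 <- c(0.5, -0.25)
  m$W2 <- matrix(c(1, 2,
                   3, -4), nrow = 2, byrow = TRUE)
  m$b2 <- c(-1, 0.1)
  m$trained <- TRUE
  feats <- structure(list(
    x = matrix(c(1, 2, 7,    # row 1: x = (1,2,7)
                 4, 1, 0),   # row 2: x = (4,1,0)
               nrow = 2, byrow = TRUE),
    bins = 1L, cfg = small_cfg(), origin_length = 10L, rate = small_rate
  ), class = "context_features")
  out <- forward(m, feats)
  # row 1: h = relu(c(1+0.5, 2-1-0.25)) = c(1.5, 0.75)
  #        y = relu(c(1.5 + 3*0.75 - 1, 2*1.5 - 4*0.75 + 0.1)) = c(2.75, 0.1)
  # row 2: h = relu(c(4.5, -3.25)) = c(4.5, 0)
  #        y = relu(c(4.5 - 1, 9 + 0.1)) = c(3.5, 9.1)
  expect_equal(as.numeric(out$vocal$m), c(2.75, 3.5))
  expect_equal(as.numeric(out$instruments$m), c(0.1, 9.1))
})

test_that("training history follows the learning-rate schedule and shrinks the loss", {
  pairs <- lapply(1:2, function(i) gen_disjoint_pair(1, seed = i,
                                                     rate = small_rate))
  fit <- train_separator(pairs, train_config(epochs = 3, seed = 0),
                         small_cfg(), hidden = 16)
  expect_equal(nrow(fit$history), 3L)
  expect_equal(fit$history$lr, 0.005 * 0.9^(0:2))
  expect_lt(fit$history$loss[3], fit$history$loss[1])
  expect_true(fit$model$trained)
  expect_gt(fit$model$scale, 0)
  expect_error(train_separator(list(), train_config()), "non-empty")
})

test_that("training is bit-deterministic given the seed", {
  pairs <- list(gen_disjoint_pair(0.8, seed = 5, rate = small_rate))
  cfg <- train_config(epochs = 2, seed = 42)
  f1 <- train_separator(pairs, cfg, small_cfg(), hidden = 8)
  f2 <- train_separator(pairs, cfg, small_cfg(), hidden = 8)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$model$W1, f2$model$W1)
})

test_that("separate() returns estimates of the mixture length; silence in, silence out", {
  cfg <- small_cfg()
  m <- random_model(n_bins(cfg), hidden = 8)
  mix <- random_signal(3100, seed = 7)
  est <- separate(m, mix, cfg)
  expect_s3_class(est, "source_pair")
  expect_length(est$vocal$samples, 3100)
  expect_length(est$instruments$samples, 3100)

  silent <- separate(m, audio_signal(numeric(2000), small_rate), cfg)
  expect_true(all(abs(silent$vocal$samples) < 1e-12))
  expect_true(all(abs(silent$instruments$samples) < 1e-12))

  um <- separator_model(bins = n_bins(cfg), hidden = 4)
  expect_error(separate(um, mix, cfg), "untrained")
  bad <- random_model(n_bins(cfg), hidden = 4); bad$W1[1] <- NaN
  expect_error(separate(bad, mix, cfg), "finite")
})

test_that("magnitudes summing to |X| resynthesize back to the mixture", {
  cfg <- small_cfg()
  mix <- random_signal(2600, seed = 9)
  spec <- stft(mix, cfg)
  mag <- magnitude(spec)
  a <- mag; a$m <- 0.3 * mag$m
  b <- mag; b$m <- 0.7 * mag$m
  back <- resynthesize_with_mixture_phase(a, spec)$samples +
    resynthesize_with_mixture_phase(b, spec)$samples
  expect_lt(signal_rms(back - mix$samples) / signal_rms(mix), 1e-9)
})

test_that("checkpoints round-trip through save/load", {
  m <- random_model(n_bins(small_cfg()), hidden = 8, seed = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  save_separator(m, path)
  m2 <- load_separator(path)
  expect_identical(m2$W1, m$W1)
  expect_identical(m2$scale, m$scale)
  expect_s3_class(m2, "separator_model")
  broken <- readRDS(path); broken$version <- "other"
  saveRDS(broken, path)
  expect_error(load_separator(path), "version")
})

test_that("chunking cuts 30-s pieces and drops the remainder", {
  rate <- 1000  # fast stand-in rate; chunking is rate-agnostic
  tr <- source_pair(random_signal(95 * rate, rate = rate, seed = 1),
                    random_signal(95 * rate, rate = rate, seed = 2),
                    id = "t")
  split <- chunk_and_split(list(tr), chunk_s = 30, seed = 1)
  chunks <- c(split$train, split$validation, split$test)
  expect_length(chunks, 3L)
  expect_true(all(vapply(chunks, function(p) length(p$mixture$samples),
                         numeric(1)) == 30 * rate))
})

test_that("10 tracks split 6/2/2 by track, deterministically", {
  rate <- 500
  tracks <- lapply(1:10, function(i) {
    source_pair(random_signal(5 * rate, rate = rate, seed = i),
                random_signal(5 * rate, rate = rate, seed = 100 + i),
                id = sprintf("tr%02d", i))
  })
  s1 <- chunk_and_split(tracks, chunk_s = 30, seed = 7)
  expect_length(s1$train, 6L)
  expect_length(s1$validation, 2L)
  expect_length(s1$test, 2L)
  # partition is disjoint and exhaustive
  ids <- sort(vapply(c(s1$train, s1$validation, s1$test),
                     function(p) p$id, character(1)))
  expect_equal(ids, sort(vapply(tracks, function(p) p$id, character(1))))
  s2 <- chunk_and_split(tracks, chunk_s = 30, seed = 7)
  expect_identical(s1$assignment, s2$assignment)
  s3 <- chunk_and_split(tracks, chunk_s = 30, seed = 8)
  expect_false(identical(s1$assignment$id, s3$assignment$id))
  expect_error(chunk_and_split(tracks, fractions = c(0.5, 0.2, 0.2)), "sum")
})

test_that("training separates the disjoint-band fixture", {
  run <- fixture_disjoint_run()
  hist <- run$fit$history
  # convergence: final loss well below the first epoch's
  expect_lt(hist$loss[nrow(hist)], 0.10 * hist$loss[1])
  expect_lt(median(tail(hist$loss, 5)), median(head(hist$loss, 5)))

  # held-out separation quality and capacity over the trivial baseline
  sdr <- vapply(run$test, function(p) {
    est <- separate(run$fit$model, p$mixture, stft_config())
    bss_decompose(est$vocal, list(p$vocal, p$instruments), 1)$sdr_db
  }, numeric(1))
  expect_gt(mean(sdr), 10)

  base_sdr <- vapply(run$test, function(p) {
    bss_decompose(p$mixture, list(p$vocal, p$instruments), 1)$sdr_db
  }, numeric(1))
  expect_gt(mean(sdr), mean(base_sdr) + 5)
})

test_that("dropout interpretation flag flips drop/keep probability", {
  pairs <- list(gen_disjoint_pair(0.8, seed = 6, rate = small_rate))
  f_drop <- train_separator(pairs, train_config(epochs = 1, seed = 1,
                                                dropout = 0.8),
                            small_cfg(), hidden = 8)
  f_keep <- train_separator(pairs, train_config(epochs = 1, seed = 1,
                                                dropout = 0.8,
                                                dropout_is_keep_prob = TRUE),
                            small_cfg(), hidden = 8)
  expect_false(identical(f_drop$model$W1, f_keep$model$W1))
})
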