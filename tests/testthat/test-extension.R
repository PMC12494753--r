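test_that("pairwise layers are identity-initialised with the right shape", {
  ext <- pairwise_extension(64, 5, "channel_vector", trainable = TRUE)
  expect_identical(ext$weights, rep(1.0, 5))
  expect_true(ext$trainable)

  # the EEG-style attachment: chunk 188 x 32 electrodes, immutable
  ext <- pairwise_extension(188, 32, "time_channel_matrix")
  expect_identical(dim(ext$weights), c(188L, 32L))
  expect_true(all(ext$weights == 1))
  expect_false(ext$trainable)

  ext <- pairwise_extension(1, 1, "channel_vector", trainable = TRUE)
  expect_identical(ext$weights, 1.0)

  expect_error(pairwise_extension(0, 3), "positive")
  expect_error(pairwise_extension(5, -1), "positive")
})

test_that("apply_extension multiplies element-wise and preserves shape", {
  set.seed(1)
  x <- array(rnorm(4 * 6 * 3), c(4, 6, 3))

  # fresh layer = exact identity (bit-identical, both modes)
  for (mode in c("channel_vector", "time_channel_matrix"))
    expect_identical(apply_extension(pairwise_extension(6, 3, mode), x), x)

  # hand-computed Hadamard product, t' = 2, c = 2
  ext <- pairwise_extension(2, 2, "time_channel_matrix")
  ext$weights <- matrix(c(2, 1, 0.5, 3), 2, 2)  # [[2, .5], [1, 3]]
  xi <- array(c(1, 3, 2, 4), c(1, 2, 2))        # [[1, 2], [3, 4]]
  out <- apply_extension(ext, xi)
  expect_equal(out[1, , ], matrix(c(2, 3, 1, 12), 2, 2))

  # channel weights broadcast over time; zero weights annihilate
  extc <- pairwise_extension(6, 3, "channel_vector")
  extc$weights <- c(0, 1, 2)
  out <- apply_extension(extc, x)
  expect_true(all(out[, , 1] == 0))
  expect_identical(out[, , 2], x[, , 2])
  expect_equal(out[, , 3], 2 * x[, , 3])

  expect_error(apply_extension(extc, array(0, c(2, 6, 4))), "channel mismatch")
  expect_error(apply_extension(ext, array(0, c(2, 5, 2))), "window mismatch")
})

test_that("the archive records every batch of every epoch", {
  # 48 instances, 3 classes, split 0.7 -> 33 train; batch 5 -> 7 batches
  ds <- tiny_dataset(n = 48, t = 8, c = 5, K = 3)
  cfg <- training_config(epochs = 3, batch_size = 5, seed = 7, runs = 1)
  ext <- pairwise_extension(8, 5, "channel_vector")
  res <- train_with_extension(shallow_softmax_classifier(8, 5, 3), ext, ds, cfg)
  expect_identical(dim(res$archive$entries), c(3L, 7L, 5L))
  expect_identical(res$archive$epochs, 3L)
  expect_identical(res$archive$batches_per_epoch, 7L)
  # immutable layer stays exactly 1.0 throughout
  expect_identical(res$ext$weights, rep(1.0, 5))

  # matrix mode: feature axes match t' x c
  ext <- pairwise_extension(8, 5, "time_channel_matrix")
  res <- train_with_extension(shallow_softmax_classifier(8, 5, 3), ext, ds, cfg)
  expect_identical(dim(res$archive$entries), c(3L, 7L, 8L, 5L))
})

test_that("an immutable layer does not interfere with training", {
  ds <- tiny_dataset(n = 30, t = 6, c = 2, K = 2)
  cfg <- training_config(epochs = 5, batch_size = 8, seed = 11, runs = 1)
  factory <- shallow_softmax_classifier(6, 2, 2)
  bare <- train_with_extension(factory, NULL, ds, cfg)
  ext <- pairwise_extension(6, 2, "channel_vector")
  with_ext <- train_with_extension(factory, ext, ds, cfg)
  expect_identical(bare$model, with_ext$model)
  expect_identical(bare$metrics$f1_weighted, with_ext$metrics$f1_weighted)
  expect_null(bare$archive)

  # a trainable layer, by contrast, changes the trajectory
  ext_tr <- pairwise_extension(6, 2, "channel_vector", trainable = TRUE)
  trained <- train_with_extension(factory, ext_tr, ds, cfg)
  expect_false(all(trained$ext$weights == 1))
})

test_that("archived gradients match finite differences of the batch loss", {
  ds <- tiny_dataset(n = 10, t = 3, c = 2, K = 2, seed = 5)
  cfg <- training_config(epochs = 1, batch_size = 32, seed = 3, runs = 1)
  factory <- shallow_softmax_classifier(3, 2, 2)
  ext <- pairwise_extension(3, 2, "time_channel_matrix")
  res <- train_with_extension(factory, ext, ds, cfg)

  # replay the run's RNG stream to recover the initial params and the batch
  set.seed(cfg$seed)
  sp <- pairwiseIE:::stratified_split(ds, cfg$split)
  params0 <- factory$init()
  ord <- sample(sp$train)                       # single full batch
  xb <- ds$data[ord, , , drop = FALSE]
  yb <- ds$labels[ord]

  loss_at <- function(P) {
    e <- pairwise_extension(3, 2, "time_channel_matrix")
    e$weights <- P
    z <- apply_extension(e, xb)
    fwd <- factory$forward(params0, z)
    pairwiseIE:::softmax_xent(fwd$logits, yb, 2)$loss
  }
  h <- 1e-5
  for (s in 1:3) for (j in 1:2) {
    Pp <- matrix(1, 3, 2); Pm <- matrix(1, 3, 2)
    Pp[s, j] <- 1 + h; Pm[s, j] <- 1 - h
    fd <- (loss_at(Pp) - loss_at(Pm)) / (2 * h)
    expect_equal(res$archive$entries[1, 1, s, j], fd, tolerance = 1e-4)
  }

  # channel-mode gradient is the time-sum of the cell gradients
  extc <- pairwise_extension(3, 2, "channel_vector")
  resc <- train_with_extension(factory, extc, ds, cfg)
  expect_equal(resc$archive$entries[1, 1, ],
               colSums(res$archive$entries[1, 1, , ]), tolerance = 1e-12)
})

test_that("channel permutation permutes the archive (symmetric init)", {
  ds <- tiny_dataset(n = 24, t = 5, c = 3, K = 2, seed = 9)
  perm <- c(3L, 1L, 2L)
  ds_p <- ds
  ds_p$data <- ds$data[, , perm]
  ds_p$channel_names <- ds$channel_names[perm]

  cfg <- training_config(epochs = 4, batch_size = 6, seed = 21, runs = 1)
  run <- function(d) {
    factory <- shallow_softmax_classifier(5, 3, 2, init_scale = 0.1)
    ext <- pairwise_extension(5, 3, "channel_vector")
    train_with_extension(factory, ext, d, cfg)$archive$entries
  }
  a <- run(ds); b <- run(ds_p)
  expect_equal(b, a[, , perm], tolerance = 1e-12)
})

test_that("noise-channel gradients shrink relative to signal channels", {
  # scaled-down multivariate benchmark, property over 5 seeds
  wins <- 0L
  for (s in 1:5) {
    spec <- synthetic_spec("multi_0", samples_per_class = 30,
                           time_steps = 120, seed = 100 + s)
    ds <- gen_multivariate(spec)
    cfg <- training_config(epochs = 12, batch_size = 16, seed = 100 + s,
                           runs = 1)
    ext <- pairwise_extension(120, 3, "channel_vector")
    res <- train_with_extension(shallow_softmax_classifier(120, 3, 3),
                                ext, ds, cfg)
    # per-epoch absolute gradient sums in the final 4 epochs
    tail_e <- 9:12
    asum <- function(j) sum(abs(apply(res$archive$entries[tail_e, , j,
                                                          drop = FALSE],
                                      1, sum)))
    if (asum(1) < asum(2)) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("the layer attaches to the per-step LSTM host as well", {
  set.seed(31)
  n <- 8; t_len <- 10
  data <- array(rnorm(n * t_len * 2, 0, 0.3), c(n, t_len, 2))
  labels <- matrix(rep(rep(0:1, each = t_len / 2), n), n, t_len, byrow = TRUE)
  data[, (t_len / 2 + 1):t_len, 1] <- data[, (t_len / 2 + 1):t_len, 1] + 1
  ds <- ts_dataset(data, labels, n_classes = 2)
  cfg <- training_config(epochs = 3, batch_size = 2, seed = 31, runs = 1)
  factory <- lstm_per_step_classifier(3, 2, 2, dropout = 0.2)

  ext <- pairwise_extension(t_len, 2, "time_channel_matrix")
  res <- train_with_extension(factory, ext, ds, cfg)
  expect_identical(dim(res$archive$entries), c(3L, 3L, 10L, 2L))
  expect_true(all(is.finite(res$archive$entries)))
  # immutable non-interference holds for the recurrent host too (dropout
  # RNG consumed in the same order)
  bare <- train_with_extension(factory, NULL, ds, cfg)
  expect_identical(bare$model, res$model)
})

test_that("training guards reject incompatible inputs", {
  ds <- tiny_dataset(n = 12, t = 4, c = 2, K = 2)
  cfg <- training_config(epochs = 1, batch_size = 4, runs = 1)
  expect_error(
    train_with_extension(shallow_softmax_classifier(4, 2, 2),
                         pairwise_extension(4, 3, "channel_vector"), ds, cfg),
    "incompatible")
  expect_error(
    train_with_extension(shallow_softmax_classifier(4, 2, 2),
                         pairwise_extension(5, 2, "time_channel_matrix"),
                         ds, cfg),
    "incompatible")
})

test_that("archives round-trip through the text serialisation", {
  arch <- random_archive(E = 3, B = 2, mode = "time_channel_matrix",
                         window_steps = 4, channels = 2, seed = 2)
  dir <- withr::local_tempdir()
  write_archive(arch, dir, config = training_config(runs = 1))
  back <- read_archive(dir)
  expect_equal(back$entries, arch$entries, tolerance = 1e-12)
  expect_identical(back$mode, arch$mode)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$config$epochs, 100)
})
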