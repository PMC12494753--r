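#' Training configuration
#'
#' One object fixes everything stochastic about a run: optimiser, learning
#' rate, epochs, batch size, stratified train fraction and the RNG seed that
#' drives weight initialisation, the split and batch shuffling. `runs` is the
#' number of repeat runs with different splits used by [fit()] and the
#' ablation harness (the repeat-run design of the benchmarks is 5 runs with
#' different splits).
#'
#' @param optimiser `"adam"` or `"rmsprop"`.
#' @param learning_rate step size (default 0.001, the simulated-benchmark
#'   setting).
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param split train fraction in (0, 1), stratified by class (default 0.7).
#' @param seed integer RNG seed.
#' @param runs number of repeat runs (default 5).
#' @return an object of class `"training_config"`.
#' @export
training_config <- function(optimiser = c("adam", "rmsprop"),
                            learning_rate = 0.001, epochs = 100L,
                            batch_size = 32L, split = 0.7, seed = 1L,
                            runs = 5L) {
  optimiser <- match.arg(optimiser)
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (split <= 0 || split >= 1) stop("split must lie strictly in (0, 1)")
  structure(list(optimiser = optimiser, learning_rate = learning_rate,
                 epochs = epochs, batch_size = batch_size, split = split,
                 seed = as.integer(seed), runs = as.integer(runs)),
            class = "training_config")
}

# element-wise first-order optimisers with the framework-default settings
make_optimiser <- function(kind, lr) {
  if (kind == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    list(
      init = function(params) list(m = lapply(params, function(p) p * 0),
                                   v = lapply(params, function(p) p * 0),
                                   t = 0L),
      step = function(params, grads, st) {
        st$t <- st$t + 1L
        for (nm in names(params)) {
          st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grads[[nm]]
          st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grads[[nm]]^2
          mh <- st$m[[nm]] / (1 - b1^st$t)
          vh <- st$v[[nm]] / (1 - b2^st$t)
          params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
        }
        list(params = params, state = st)
      })
  } else {  # rmsprop
    alpha <- 0.99; eps <- 1e-8
    list(
      init = function(params) list(v = lapply(params, function(p) p * 0)),
      step = function(params, grads, st) {
        for (nm in names(params)) {
          st$v[[nm]] <- alpha * st$v[[nm]] + (1 - alpha) * grads[[nm]]^2
          params[[nm]] <- params[[nm]] - lr * grads[[nm]] /
            (sqrt(st$v[[nm]]) + eps)
        }
        list(params = params, state = st)
      })
  }
}

# stratified train/validation split on instance-level labels
stratified_split <- function(dataset, split) {
  labs <- instance_labels(dataset)
  train_idx <- integer(0)
  for (k in sort(unique(labs))) {
    idx <- which(labs == k)
    n_tr <- max(1L, round(split * length(idx)))
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  list(train = sort(train_idx),
       val = setdiff(seq_along(labs), train_idx))
}

# mean cross-entropy over instances (and time steps for per-step labels);
# returns loss and dL/dlogits with the batch (x step) mean reduction applied
softmax_xent <- function(logits, labels, classes) {
  d <- dim(logits)
  if (length(d) == 3L) {
    m <- matrix(logits, d[1L] * d[2L], d[3L])
    y <- as.integer(labels)            # n x t matrix flattens column-major
  } else {
    m <- logits
    y <- as.integer(labels)
  }
  p <- softmax_rows(m)
  rows <- nrow(m)
  picked <- p[cbind(seq_len(rows), y + 1L)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dl <- p
  dl[cbind(seq_len(rows), y + 1L)] <- dl[cbind(seq_len(rows), y + 1L)] - 1
  dl <- dl / rows
  if (length(d) == 3L) dim(dl) <- d
  list(loss = loss, dlogits = dl)
}

#' Train a host classifier with an attached pairwise layer
#'
#' Runs the full pipeline `f(x) = NN(IE(x))`: the pairwise layer multiplies
#' the input, the host network classifies, and the gradient of the
#' (mean-reduced) batch loss with respect to every pairwise weight is
#' recorded for every batch of every epoch by the gradient-collection
#' module - regardless of whether the layer is trainable. A trainable layer
#' is updated by the same optimiser as the host model; an immutable layer
#' keeps every weight at exactly 1.0, so the host model trains bit-identically
#' to extension-free training under the same seed.
#'
#' @param model_factory a model factory such as
#'   [shallow_softmax_classifier()].
#' @param ext a [pairwise_extension()] matching the dataset window shape, or
#'   `NULL` to train without a layer (no archive is returned).
#' @param dataset a [ts_dataset()].
#' @param config a [training_config()].
#' @return list with elements `model` (trained host parameters), `ext` (the
#'   extension after training), `archive` (a [gradient_archive()], `NULL` if
#'   `ext` is `NULL`), `metrics` (per-epoch train/validation loss and final
#'   weighted / per-class validation F1) and `split` (train/val indices).
#' @export
train_with_extension <- function(model_factory, ext, dataset, config) {
  stopifnot(inherits(model_factory, "pie_model_factory"),
            inherits(dataset, "ts_dataset"),
            inherits(config, "training_config"))
  if (n_instances(dataset) < 2L) stop("dataset has too few instances")
  d <- dim(dataset$data)
  if (!is.null(ext)) {
    stopifnot(inherits(ext, "pairwise_extension"))
    if (ext$channels != d[3L] ||
        (ext$mode == "time_channel_matrix" && ext$window_steps != d[2L]))
      stop("extension shape is incompatible with the dataset windows")
  }
  per_step <- isTRUE(model_factory$per_step)
  if (per_step && !is.matrix(dataset$labels))
    stop("per-time-step classifier needs per-time-step labels")
  if (!per_step && is.matrix(dataset$labels))
    stop("instance classifier needs per-instance labels")

  set.seed(config$seed)
  sp <- stratified_split(dataset, config$split)
  params <- model_factory$init()
  opt <- make_optimiser(config$optimiser, config$learning_rate)
  opt_state <- opt$init(params)
  ext_opt_state <- if (!is.null(ext) && ext$trainable)
    opt$init(list(w = ext$weights)) else NULL

  n_tr <- length(sp$train)
  n_batches <- ceiling(n_tr / config$batch_size)
  archive_entries <- if (!is.null(ext)) {
    if (ext$mode == "channel_vector")
      array(0, c(config$epochs, n_batches, ext$channels))
    else array(0, c(config$epochs, n_batches, d[2L], d[3L]))
  } else NULL

  x_val <- dataset$data[sp$val, , , drop = FALSE]
  y_val <- if (per_step) dataset$labels[sp$val, , drop = FALSE]
           else dataset$labels[sp$val]
  history <- matrix(NA_real_, config$epochs, 2L,
                    dimnames = list(NULL, c("train_loss", "val_loss")))

  for (e in seq_len(config$epochs)) {
    ord <- sample(sp$train)
    epoch_loss <- 0
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * config$batch_size + 1L):
                   min(b * config$batch_size, n_tr)]
      xb <- dataset$data[idx, , , drop = FALSE]
      yb <- if (per_step) dataset$labels[idx, , drop = FALSE]
            else dataset$labels[idx]
      zb <- if (is.null(ext)) xb else apply_extension(ext, xb)
      fwd <- model_factory$forward(params, zb, training = TRUE)
      ce <- softmax_xent(fwd$logits, yb, dataset$n_classes)
      if (!is.finite(ce$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", e))
      bwd <- model_factory$backward(params, zb, fwd$cache, ce$dlogits)
      epoch_loss <- epoch_loss + ce$loss * length(idx)

      if (!is.null(ext)) {
        g_ext <- pairwise_gradient(ext, xb, bwd$dx)
        if (ext$mode == "channel_vector")
          archive_entries[e, b, ] <- g_ext
        else archive_entries[e, b, , ] <- g_ext
        if (ext$trainable) {
          up <- opt$step(list(w = ext$weights), list(w = g_ext),
                         ext_opt_state)
          ext$weights <- up$params$w
          ext_opt_state <- up$state
        }
      }
      up <- opt$step(params, bwd$grads, opt_state)
      params <- up$params
      opt_state <- up$state
    }
    history[e, "train_loss"] <- epoch_loss / n_tr
    vf <- model_factory$forward(params, if (is.null(ext)) x_val
                                else apply_extension(ext, x_val))
    history[e, "val_loss"] <- softmax_xent(vf$logits, y_val,
                                           dataset$n_classes)$loss
  }

  probs <- predict_proba(model_factory, params, x_val)
  preds <- if (per_step) {
    pd <- dim(probs)
    matrix(max.col(matrix(probs, pd[1L] * pd[2L], pd[3L])) - 1L,
           pd[1L], pd[2L])
  } else max.col(probs) - 1L
  f1 <- f1_scores(as.integer(preds), as.integer(y_val), dataset$n_classes)

  archive <- if (!is.null(ext))
    gradient_archive(archive_entries, ext$mode, d[2L], d[3L]) else NULL
  list(model = params, ext = ext, archive = archive,
       metrics = list(history = history, f1_weighted = f1$weighted,
                      f1_per_class = f1$per_class),
       split = sp, factory = model_factory, config = config)
}

#' Fit a classifier (optionally with a pairwise layer), with repeat runs
#'
#' Thin orchestration over [train_with_extension()]. With `config$runs > 1`
#' the model is fitted `runs` times with seeds `seed, seed + 1, ...` (each
#' seed drives a fresh stratified split, weight initialisation and batch
#' order), and a list of run results is returned.
#'
#' @param model_factory a model factory.
#' @param dataset a [ts_dataset()].
#' @param config a [training_config()].
#' @param ext optional [pairwise_extension()].
#' @return a single run result (`runs == 1`) or a list of them with class
#'   `"pie_fit_runs"`.
#' @export
fit <- function(model_factory, dataset, config, ext = NULL) {
  if (config$runs == 1L)
    return(train_with_extension(model_factory, ext, dataset, config))
  runs <- lapply(seq_len(config$runs) - 1L, function(r) {
    cfg <- config; cfg$seed <- config$seed + r; cfg$runs <- 1L
    train_with_extension(model_factory, ext, dataset, cfg)
  })
  structure(runs, class = "pie_fit_runs")
}
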