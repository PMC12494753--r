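#' Shallow softmax host classifier
#'
#' The reference architecture for the simulated benchmarks: the window is
#' flattened and mapped by a single linear layer to class logits; softmax
#' gives class probabilities. Gradients are exact closed forms, so the
#' archived pairwise gradients are analytically checkable.
#'
#' @param input_steps window length `t'`.
#' @param channels number of channels `c`.
#' @param classes number of classes `K`.
#' @param init_scale `NULL` for seeded Glorot-uniform initialisation
#'   (the default), or a single number to fill every weight with that
#'   constant (bias zero). A constant init is channel-symmetric, which makes
#'   channel-permutation equivariance of the training trajectory exact.
#' @return a model factory (class `"pie_model_factory"`) understood by
#'   [fit()] and [train_with_extension()].
#' @export
shallow_softmax_classifier <- function(input_steps, channels, classes,
                                       init_scale = NULL) {
  input_steps <- as.integer(input_steps); channels <- as.integer(channels)
  classes <- as.integer(classes)
  if (input_steps < 1L || channels < 1L || classes < 2L)
    stop("dimensions must be positive (and classes >= 2)")
  p_in <- input_steps * channels

  init <- function() {
    W <- if (is.null(init_scale)) {
      lim <- sqrt(6 / (p_in + classes))
      matrix(stats::runif(p_in * classes, -lim, lim), p_in, classes)
    } else matrix(init_scale, p_in, classes)
    list(W = W, b = numeric(classes))
  }
  forward <- function(params, x, training = FALSE) {
    d <- dim(x)
    xf <- matrix(x, d[1L], d[2L] * d[3L])
    logits <- xf %*% params$W + rep(params$b, each = d[1L])
    list(logits = logits, cache = list(xf = xf, dims = d))
  }
  backward <- function(params, x, cache, dlogits) {
    gW <- crossprod(cache$xf, dlogits)
    gb <- colSums(dlogits)
    dx <- dlogits %*% t(params$W)
    dim(dx) <- cache$dims
    list(grads = list(W = gW, b = gb), dx = dx)
  }
  structure(list(input_steps = input_steps, channels = channels,
                 classes = classes, per_step = FALSE,
                 init = init, forward = forward, backward = backward,
                 name = "shallow_softmax"),
            class = "pie_model_factory")
}

#' Per-time-step LSTM host classifier
#'
#' A single LSTM layer followed by (optional) dropout and a linear softmax
#' output applied at every time step, emitting a `t' x K` probability matrix
#' per window - the architecture used for per-time-step labelled windows
#' (e.g. hidden size 2 with dropout 0.2 for the occupancy-style setup,
#' hidden size 64 for the activity-recognition-style setup). Forward and
#' backward passes (full backpropagation through time, including the
#' gradient with respect to the input needed by the pairwise layer) are
#' implemented directly.
#'
#' Dropout is active only during training (`training = TRUE`); evaluation is
#' deterministic.
#'
#' @param hidden_units LSTM hidden state size (>= 1).
#' @param channels number of input channels `c`.
#' @param classes number of classes `K`.
#' @param dropout dropout probability on the hidden state before the output
#'   layer (default 0).
#' @return a model factory (class `"pie_model_factory"`).
#' @export
lstm_per_step_classifier <- function(hidden_units, channels, classes,
                                     dropout = 0) {
  h <- as.integer(hidden_units); channels <- as.integer(channels)
  classes <- as.integer(classes)
  if (h < 1L || channels < 1L || classes < 2L)
    stop("dimensions must be positive (and classes >= 2)")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")

  init <- function() {
    k <- 1 / sqrt(h)
    u <- function(n) stats::runif(n, -k, k)
    list(Wx = matrix(u(channels * 4L * h), channels, 4L * h),
         Wh = matrix(u(h * 4L * h), h, 4L * h),
         bh = u(4L * h),
         Wy = matrix(u(h * classes), h, classes),
         by = numeric(classes))
  }
  sigm <- function(z) 1 / (1 + exp(-z))
  gate_idx <- function() list(i = 1:h, f = (h + 1):(2 * h),
                              g = (2 * h + 1):(3 * h), o = (3 * h + 1):(4 * h))

  forward <- function(params, x, training = FALSE) {
    d <- dim(x); b <- d[1L]; t_len <- d[2L]
    gi <- gate_idx()
    hs <- array(0, c(b, t_len, h)); cs <- array(0, c(b, t_len, h))
    gates <- array(0, c(b, t_len, 4L * h))
    h_prev <- matrix(0, b, h); c_prev <- matrix(0, b, h)
    for (s in seq_len(t_len)) {
      xt <- matrix(x[, s, ], b, channels)
      a <- xt %*% params$Wx + h_prev %*% params$Wh +
        rep(params$bh, each = b)
      ig <- sigm(a[, gi$i, drop = FALSE]); fg <- sigm(a[, gi$f, drop = FALSE])
      gg <- tanh(a[, gi$g, drop = FALSE]); og <- sigm(a[, gi$o, drop = FALSE])
      c_new <- fg * c_prev + ig * gg
      h_new <- og * tanh(c_new)
      gates[, s, ] <- cbind(ig, fg, gg, og)
      cs[, s, ] <- c_new; hs[, s, ] <- h_new
      h_prev <- h_new; c_prev <- c_new
    }
    # dropout on the hidden representation feeding the output layer
    drop_mask <- NULL
    hs_out <- hs
    if (training && dropout > 0) {
      drop_mask <- array(stats::rbinom(b * t_len * h, 1L, 1 - dropout) /
                           (1 - dropout), c(b, t_len, h))
      hs_out <- hs * drop_mask
    }
    hflat <- matrix(hs_out, b * t_len, h)
    logits <- hflat %*% params$Wy + rep(params$by, each = b * t_len)
    dim(logits) <- c(b, t_len, classes)
    list(logits = logits,
         cache = list(hs = hs, cs = cs, gates = gates, dims = d,
                      drop_mask = drop_mask, hs_out = hs_out))
  }

  backward <- function(params, x, cache, dlogits) {
    d <- cache$dims; b <- d[1L]; t_len <- d[2L]
    gi <- gate_idx()
    dflat <- matrix(dlogits, b * t_len, classes)
    hflat <- matrix(cache$hs_out, b * t_len, h)
    gWy <- crossprod(hflat, dflat)
    gby <- colSums(dflat)
    dh_out <- dflat %*% t(params$Wy)
    dim(dh_out) <- c(b, t_len, h)
    if (!is.null(cache$drop_mask)) dh_out <- dh_out * cache$drop_mask

    gWx <- matrix(0, channels, 4L * h); gWh <- matrix(0, h, 4L * h)
    gbh <- numeric(4L * h)
    dx <- array(0, d)
    dh_next <- matrix(0, b, h); dc_next <- matrix(0, b, h)
    for (s in rev(seq_len(t_len))) {
      ig <- matrix(cache$gates[, s, gi$i], b, h)
      fg <- matrix(cache$gates[, s, gi$f], b, h)
      gg <- matrix(cache$gates[, s, gi$g], b, h)
      og <- matrix(cache$gates[, s, gi$o], b, h)
      c_t <- matrix(cache$cs[, s, ], b, h)
      c_prev <- if (s > 1L) matrix(cache$cs[, s - 1L, ], b, h)
                else matrix(0, b, h)
      h_prev <- if (s > 1L) matrix(cache$hs[, s - 1L, ], b, h)
                else matrix(0, b, h)
      dh <- matrix(dh_out[, s, ], b, h) + dh_next
      tc <- tanh(c_t)
      dc <- dh * og * (1 - tc^2) + dc_next
      da <- cbind(dc * gg * ig * (1 - ig),          # input gate (pre-act)
                  dc * c_prev * fg * (1 - fg),      # forget gate
                  dc * ig * (1 - gg^2),             # candidate
                  dh * tc * og * (1 - og))          # output gate
      xt <- matrix(x[, s, ], b, channels)
      gWx <- gWx + crossprod(xt, da)
      gWh <- gWh + crossprod(h_prev, da)
      gbh <- gbh + colSums(da)
      dx[, s, ] <- da %*% t(params$Wx)
      dh_next <- da %*% t(params$Wh)
      dc_next <- dc * fg
    }
    list(grads = list(Wx = gWx, Wh = gWh, bh = gbh, Wy = gWy, by = gby),
         dx = dx)
  }

  structure(list(input_steps = NA_integer_, channels = channels,
                 classes = classes, per_step = TRUE,
                 init = init, forward = forward, backward = backward,
                 name = "lstm_per_step", hidden_units = h, dropout = dropout),
            class = "pie_model_factory")
}

#' Class probabilities from a trained model
#'
#' @param factory the model factory used in training.
#' @param params trained parameters (the `model` element of a fit).
#' @param x input array `batch x t' x c`.
#' @return probabilities: `batch x K` matrix, or `batch x t' x K` array for
#'   per-time-step classifiers. Rows sum to 1.
#' @export
predict_proba <- function(factory, params, x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  logits <- factory$forward(params, x, training = FALSE)$logits
  softmax_last(logits)
}

# row-wise softmax over the last axis of a matrix or 3-d array
softmax_last <- function(logits) {
  d <- dim(logits)
  if (length(d) == 3L) {
    m <- matrix(logits, d[1L] * d[2L], d[3L])
    p <- softmax_rows(m)
    array(p, d)
  } else softmax_rows(logits)
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Reference hyper-parameters for a compact convolutional EEG classifier
#'
#' Configuration stub recording the hyper-parameters of the compact
#' convolutional EEG architecture (and its LSTM-augmented variant) used as a
#' host network in EEG error-decoding experiments. The architecture itself is
#' not implemented here - it requires external EEG recordings to exercise -
#' but the recorded configuration documents how the pairwise layer would be
#' attached (a `time_channel_matrix` extension of shape chunk x electrodes).
#'
#' @return a named list of hyper-parameters.
#' @export
eegnet_reference_config <- function() {
  list(electrodes = 32L, chunk_size = 188L, classes = 2L,
       K1 = 32L, K2 = 32L, F1 = 8L, F2 = 16L, D = 2L, dropout = 0.5,
       lstm_hidden = 188L, implemented = FALSE)
}
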