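#' Importance estimate container
#'
#' Per-feature non-negative scores `s_x` and the descending ranking `R`.
#' Features are channels, time steps, or (time step, channel) cells depending
#' on `feature_axis`. The ranking is the permutation of feature indices that
#' sorts scores non-increasingly, with ties broken by ascending feature
#' index (stable).
#'
#' @param scores numeric vector of per-feature scores (cell scores are
#'   flattened column-major, time fastest).
#' @param method one of `"weight_naive"`, `"grad_auc"`, `"grad_roc"`,
#'   `"grad_std"`.
#' @param feature_axis one of `"channel"`, `"time_step"`,
#'   `"time_channel_cell"`.
#' @param feature_labels optional character labels.
#' @param dims for cell estimates, `c(t', c)`.
#' @return an object of class `"importance_estimate"`.
#' @export
importance_estimate <- function(scores, method, feature_axis,
                                feature_labels = NULL, dims = NULL) {
  scores <- as.numeric(scores)
  if (!length(scores)) stop("scores must be non-empty")
  if (is.null(feature_labels)) feature_labels <- as.character(seq_along(scores) - 1L)
  ranking <- order(-scores, seq_along(scores))
  structure(list(scores = scores, ranking = ranking, method = method,
                 feature_axis = feature_axis,
                 feature_labels = feature_labels, dims = dims),
            class = "importance_estimate")
}

#' @export
print.importance_estimate <- function(x, ...) {
  cat(sprintf("<importance_estimate> %s over %s (%d features)\n",
              x$method, x$feature_axis, length(x$scores)))
  top <- utils::head(x$ranking, 5L)
  cat("  top:", paste(sprintf("%s=%.4g", x$feature_labels[top],
                              x$scores[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Importance from trained pairwise weights (Weight-Naive)
#'
#' Scores are the absolute magnitudes of the trained pairwise weights, ranked
#' in descending order. Only meaningful for a layer trained with
#' `trainable = TRUE`; an all-ones (untrained/immutable) layer yields equal
#' scores and a degenerate index-order ranking, which is signalled with a
#' warning.
#'
#' @param ext a [pairwise_extension()] after training.
#' @return an [importance_estimate()] over channels (channel mode) or cells
#'   (matrix mode).
#' @export
weight_naive_scores <- function(ext) {
  stopifnot(inherits(ext, "pairwise_extension"))
  w <- ext$weights
  if (all(w == 1))
    warning("pairwise weights are all 1.0 (untrained or immutable layer); ",
            "weight-naive scores are degenerate")
  if (ext$mode == "channel_vector") {
    importance_estimate(abs(w), "weight_naive", "channel",
                        feature_labels = paste0("ch", seq_along(w) - 1L))
  } else {
    axis <- if (ext$channels == 1L) "time_step" else "time_channel_cell"
    importance_estimate(abs(as.numeric(w)), "weight_naive", axis,
                        feature_labels = cell_labels(ext$window_steps,
                                                     ext$channels),
                        dims = c(ext$window_steps, ext$channels))
  }
}

cell_labels <- function(t_len, c_len) {
  if (c_len == 1L) paste0("t", seq_len(t_len) - 1L)
  else as.vector(outer(seq_len(t_len) - 1L, seq_len(c_len) - 1L,
                       function(s, j) sprintf("t%d_ch%d", s, j)))
}

#' Build a per-epoch gradient profile from an archive
#'
#' The gradient profile of feature `f` is the sequence, over epochs, of an
#' epoch aggregate of that feature's per-batch gradients: the within-epoch
#' sum (`gamma = "sum"`, the AUC/ROC setting) or the sample standard
#' deviation across batches (`gamma = "std"`, divisor B-1; a single batch
#' per epoch yields a zero profile with a warning).
#'
#' When `feature_axis = "channel"` is requested from a matrix-mode archive,
#' cell gradients are first summed over the time axis (the channel-shared
#' weight's gradient is exactly the time-sum of the cell gradients) before
#' applying `gamma`.
#'
#' @param archive a [gradient_archive()].
#' @param gamma `"sum"` or `"std"`.
#' @param feature_axis `"channel"`, `"time_step"` (matrix archives with one
#'   channel) or `"time_channel_cell"`.
#' @return an object of class `"gradient_profile"`: list with `values`
#'   (E x F matrix), `gamma`, `feature_axis`, `dims`.
#' @export
build_profile <- function(archive, gamma = c("sum", "std"),
                          feature_axis = c("channel", "time_step",
                                           "time_channel_cell")) {
  stopifnot(inherits(archive, "gradient_archive"))
  gamma <- match.arg(gamma)
  feature_axis <- match.arg(feature_axis)
  E <- archive$epochs; B <- archive$batches_per_epoch
  ent <- archive$entries

  if (archive$mode == "channel_vector") {
    if (feature_axis != "channel")
      stop("a channel-vector archive only supports feature_axis = 'channel'")
    g <- array(ent, c(E, B, archive$channels))
  } else {
    if (feature_axis == "channel") {
      # reduce cells to channels: sum gradients over the time axis
      g <- array(0, c(E, B, archive$channels))
      for (j in seq_len(archive$channels)) {
        slab <- array(ent[, , , j], c(E, B, archive$window_steps))
        g[, , j] <- rowSums(slab, dims = 2L)
      }
    } else if (feature_axis == "time_step") {
      if (archive$channels != 1L)
        stop("feature_axis = 'time_step' needs a single-channel archive")
      g <- array(ent, c(E, B, archive$window_steps))
    } else {
      g <- array(ent, c(E, B, archive$window_steps * archive$channels))
    }
  }

  f_len <- dim(g)[3L]
  if (gamma == "std" && B == 1L) {
    warning("gamma = 'std' with a single batch per epoch yields a zero profile")
    values <- matrix(0, E, f_len)
  } else if (gamma == "sum") {
    values <- apply(g, c(1L, 3L), sum)
  } else {
    values <- apply(g, c(1L, 3L), stats::sd)
  }
  dims <- if (feature_axis == "time_channel_cell")
    c(archive$window_steps, archive$channels) else NULL
  structure(list(values = matrix(values, E, f_len), gamma = gamma,
                 feature_axis = feature_axis, dims = dims,
                 channels = archive$channels,
                 window_steps = archive$window_steps),
            class = "gradient_profile")
}

#' Trapezoidal area under a per-epoch profile
#'
#' Unit epoch spacing; a length-1 profile returns its single value.
#'
#' @param v numeric sequence over epochs.
#' @return scalar area.
#' @export
profile_auc <- function(v) {
  if (!length(v)) stop("empty profile")
  if (length(v) == 1L) return(v[[1L]])
  sum((v[-1L] + v[-length(v)]) / 2)
}

#' Epoch-to-epoch rate of change of a profile
#'
#' First differences with the first epoch's value retained as the first
#' element: `(v1, v2 - v1, ..., vE - v[E-1])`. The plain sum of the result
#' telescopes back to `vE`.
#'
#' @param v numeric sequence over at least 2 epochs.
#' @return numeric sequence of the same length.
#' @export
profile_roc <- function(v) {
  if (length(v) < 2L) stop("rate-of-change needs at least 2 epochs")
  c(v[[1L]], diff(v))
}

#' Gradient-profile importance scores (Grad-AUC / Grad-ROC / Grad-STD)
#'
#' * `grad_auc`: `s_x = |AUC(G^x)|` with the within-epoch sum profile.
#' * `grad_roc`: `s_x = |AUC(ROC(G^x))|` with the sum profile.
#' * `grad_std`: `s_x = AUC(G^x)` with the across-batch standard-deviation
#'   profile (non-negative by construction, no absolute value taken).
#'
#' @param archive a [gradient_archive()] from a completed training run.
#' @param method `"grad_auc"`, `"grad_roc"` or `"grad_std"`.
#' @param feature_axis as in [build_profile()].
#' @return an [importance_estimate()].
#' @export
grad_scores <- function(archive,
                        method = c("grad_auc", "grad_roc", "grad_std"),
                        feature_axis = c("channel", "time_step",
                                         "time_channel_cell")) {
  method <- match.arg(method)
  feature_axis <- match.arg(feature_axis)
  gamma <- if (method == "grad_std") "std" else "sum"
  prof <- build_profile(archive, gamma, feature_axis)
  scores <- apply(prof$values, 2L, function(v) {
    switch(method,
           grad_auc = abs(profile_auc(v)),
           grad_roc = abs(profile_auc(profile_roc(v))),
           grad_std = profile_auc(v))
  })
  labels <- if (feature_axis == "channel")
    paste0("ch", seq_len(archive$channels) - 1L)
  else cell_labels(prof$window_steps, prof$channels)[
    seq_len(ncol(prof$values))]
  importance_estimate(scores, method, feature_axis,
                      feature_labels = labels, dims = prof$dims)
}

#' Aggregate per-cell importance along the time axis (AHP)
#'
#' Reduces a `t' x c` cell estimate from the Hadamard-product layer to `c`
#' channel scores by taking the mean over the time axis of each channel
#' (the sum gives identical rankings; the mean keeps scales comparable
#' across window lengths).
#'
#' @param cell_estimate an [importance_estimate()] with
#'   `feature_axis = "time_channel_cell"` (or `"time_step"` with one
#'   channel).
#' @param window_steps,channels the `t' x c` layout of the cell scores;
#'   defaults to the estimate's own `dims`.
#' @return an [importance_estimate()] over channels.
#' @export
ahp_aggregate <- function(cell_estimate, window_steps = NULL,
                          channels = NULL) {
  stopifnot(inherits(cell_estimate, "importance_estimate"))
  if (!cell_estimate$feature_axis %in% c("time_channel_cell", "time_step"))
    stop("ahp_aggregate needs a per-cell (or per-time-step) estimate")
  dims <- cell_estimate$dims
  if (is.null(window_steps)) window_steps <- dims[1L]
  if (is.null(channels)) channels <- dims[2L]
  if (is.null(window_steps) || is.null(channels) ||
      window_steps * channels != length(cell_estimate$scores))
    stop("cell scores do not reshape to t' x c")
  m <- matrix(cell_estimate$scores, window_steps, channels)
  importance_estimate(colMeans(m), cell_estimate$method, "channel",
                      feature_labels = paste0("ch", seq_len(channels) - 1L))
}
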