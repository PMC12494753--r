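#' Identity-initialised pairwise layer
#'
#' A pairwise layer is a diagonal linear map: one trainable weight per input
#' entry, applied by element-wise multiplication. Two multivariate modes are
#' supported:
#'
#' * `"channel_vector"` - one weight per channel, shared across time steps
#'   (element-wise multiplication upon the data channels); yields channel
#'   importance.
#' * `"time_channel_matrix"` - a full `t' x c` weight matrix (Hadamard
#'   product); yields per-(time step, channel) cell importance, which can be
#'   aggregated along the time axis ([ahp_aggregate()]).
#'
#' Every weight is initialised to exactly 1.0 so the layer starts as the
#' identity function: all features share the same reference point and the
#' host model's forward pass is bit-identical to running without the layer.
#' With `trainable = FALSE` the weights stay exactly 1.0 throughout training
#' (the update step is suppressed, not the gradient computation), and only
#' the gradient trajectory is observed.
#'
#' @param window_steps window length `t'` (>= 1).
#' @param channels number of channels `c` (>= 1).
#' @param mode `"channel_vector"` or `"time_channel_matrix"`.
#' @param trainable if `FALSE` (the default, the gradient-profile setting)
#'   the weights are immutable.
#' @return an object of class `"pairwise_extension"`.
#' @export
pairwise_extension <- function(window_steps, channels,
                               mode = c("channel_vector",
                                        "time_channel_matrix"),
                               trainable = FALSE) {
  mode <- match.arg(mode)
  window_steps <- as.integer(window_steps); channels <- as.integer(channels)
  if (is.na(window_steps) || window_steps < 1L)
    stop("window_steps must be a positive integer")
  if (is.na(channels) || channels < 1L)
    stop("channels must be a positive integer")
  weights <- if (mode == "channel_vector") rep(1.0, channels)
             else matrix(1.0, window_steps, channels)
  structure(list(mode = mode, weights = weights,
                 window_steps = window_steps, channels = channels,
                 trainable = isTRUE(trainable)),
            class = "pairwise_extension")
}

#' @export
print.pairwise_extension <- function(x, ...) {
  cat(sprintf("<pairwise_extension> mode=%s t'=%d c=%d %s\n", x$mode,
              x$window_steps, x$channels,
              if (x$trainable) "trainable" else "immutable"))
  invisible(x)
}

# number of scalar features the layer exposes
n_features <- function(ext) {
  if (ext$mode == "channel_vector") ext$channels
  else ext$window_steps * ext$channels
}

#' Apply a pairwise layer to a batch of windows
#'
#' @param ext a `pairwise_extension`.
#' @param x numeric array `batch x t' x c` (a `batch x t'` matrix is accepted
#'   for `c = 1`).
#' @return array of the same shape: `x[i,s,j] * C[j]` (channel mode) or
#'   `x[i,s,j] * P[s,j]` (matrix mode).
#' @export
apply_extension <- function(ext, x) {
  stopifnot(inherits(ext, "pairwise_extension"))
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(d) != 3L) stop("x must be a batch x t' x c array")
  if (d[3L] != ext$channels)
    stop(sprintf("channel mismatch: x has %d channels, extension has %d",
                 d[3L], ext$channels))
  if (ext$mode == "time_channel_matrix" && d[2L] != ext$window_steps)
    stop(sprintf("window mismatch: x has %d steps, extension has %d",
                 d[2L], ext$window_steps))
  if (ext$mode == "channel_vector") {
    # recycle one weight per channel across batch and time
    x * rep(ext$weights, each = d[1L] * d[2L])
  } else {
    # P[s,j] recycled across the batch axis (column-major layout)
    x * rep(ext$weights, each = d[1L])
  }
}

# gradient of the batch loss w.r.t. the pairwise weights, given the raw
# input x and dz = dL/d(extension output): g[s,j] = sum_i x[i,s,j]*dz[i,s,j],
# further summed over time in channel mode (the EWM weight is shared)
pairwise_gradient <- function(ext, x, dz) {
  d <- dim(x)
  g_cells <- colSums(matrix(x * dz, d[1L], d[2L] * d[3L]))
  if (ext$mode == "channel_vector") {
    colSums(matrix(g_cells, d[2L], d[3L]))
  } else {
    matrix(g_cells, d[2L], d[3L])
  }
}

#' Archive of pairwise-weight gradients collected during training
#'
#' Dense array of the optimiser-visible gradient of the (mean-reduced) batch
#' loss with respect to every pairwise weight, for every batch of every
#' epoch, captured before any optimiser-state transformation.
#'
#' @param entries numeric array `epochs x batches x c` (channel mode) or
#'   `epochs x batches x t' x c` (matrix mode).
#' @param mode the extension mode the gradients belong to.
#' @param window_steps,channels layer dimensions.
#' @return an object of class `"gradient_archive"`.
#' @export
gradient_archive <- function(entries, mode, window_steps, channels) {
  d <- dim(entries)
  expected <- if (mode == "channel_vector") 3L else 4L
  if (length(d) != expected)
    stop("entries rank does not match the extension mode")
  if (mode == "channel_vector" && d[3L] != channels)
    stop("entries feature axis does not match channels")
  if (mode == "time_channel_matrix" &&
      (d[3L] != window_steps || d[4L] != channels))
    stop("entries feature axes do not match t' x c")
  structure(list(entries = entries, mode = mode,
                 epochs = d[1L], batches_per_epoch = d[2L],
                 window_steps = as.integer(window_steps),
                 channels = as.integer(channels)),
            class = "gradient_archive")
}

#' @export
print.gradient_archive <- function(x, ...) {
  cat(sprintf("<gradient_archive> %s: %d epochs x %d batches x %s\n",
              x$mode, x$epochs, x$batches_per_epoch,
              if (x$mode == "channel_vector") sprintf("%d channels", x$channels)
              else sprintf("%d x %d cells", x$window_steps, x$channels)))
  invisible(x)
}

# archive entries as an (epochs x batches) x F matrix with F the flattened
# feature axis (channels, or t' x c cells column-major)
archive_matrix <- function(archive) {
  e <- archive$entries
  d <- dim(e)
  matrix(e, d[1L] * d[2L], prod(d[-(1:2)]))
}
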