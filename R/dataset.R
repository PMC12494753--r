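#' Labelled windowed time-series dataset
#'
#' The canonical container used throughout the package: a numeric array of
#' shape instances x time steps x channels, with integer class labels either
#' per instance (length n) or per time step (n x t matrix), and an optional
#' ground-truth importance mask over the (time step, channel) grid.
#'
#' Labels are 0-based (`0 .. n_classes - 1`), matching the convention of the
#' classifiers in this package. Channel indices in the API are 1-based (R
#' convention); default channel names are `"ch0" .. "ch<c-1>"` so that the
#' first channel of the multivariate benchmarks is the noise channel `"ch0"`.
#'
#' @param data numeric array `n x t x c`.
#' @param labels integer vector of length `n` (per-instance) or integer
#'   matrix `n x t` (per-time-step), values in `0 .. n_classes - 1`.
#' @param n_classes number of classes `K`; inferred from labels if missing.
#' @param truth_mask optional logical `t x c` matrix marking ground-truth
#'   important cells; must contain at least one `TRUE` cell when given.
#' @param channel_names character vector of length `c`.
#' @return an object of class `"ts_dataset"`.
#' @export
ts_dataset <- function(data, labels, n_classes = NULL, truth_mask = NULL,
                       channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (instances x time steps x channels)")
  storage.mode(data) <- "double"
  d <- dim(data)
  n <- d[1L]; t_len <- d[2L]; c_len <- d[3L]

  per_step <- is.matrix(labels)
  if (per_step) {
    if (!all(dim(labels) == c(n, t_len)))
      stop("per-time-step labels must be an n x t matrix")
  } else {
    if (length(labels) != n)
      stop("per-instance labels must have length n")
  }
  lab_vals <- as.integer(labels)
  if (anyNA(lab_vals)) stop("labels must be integer class codes")
  if (is.null(n_classes)) n_classes <- max(lab_vals) + 1L
  n_classes <- as.integer(n_classes)
  if (any(lab_vals < 0L) || any(lab_vals >= n_classes))
    stop("labels must lie in 0 .. n_classes - 1")
  if (length(unique(lab_vals)) < n_classes)
    stop("every class must be present at least once")
  labels <- if (per_step) matrix(lab_vals, n, t_len) else lab_vals

  if (!is.null(truth_mask)) {
    truth_mask <- as.matrix(truth_mask)
    if (!all(dim(truth_mask) == c(t_len, c_len)))
      stop("truth_mask must be a t x c logical matrix")
    storage.mode(truth_mask) <- "logical"
    if (!any(truth_mask))
      stop("truth_mask must mark at least one cell")
  }
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(c_len) - 1L)
  if (length(channel_names) != c_len)
    stop("channel_names must have length c")

  structure(
    list(data = data, labels = labels, n_classes = n_classes,
         truth_mask = truth_mask, channel_names = as.character(channel_names)),
    class = "ts_dataset")
}

#' @export
print.ts_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_dataset> %d instances x %d steps x %d channels, %d classes\n",
              d[1L], d[2L], d[3L], x$n_classes))
  cat(sprintf("  labels: %s; truth mask: %s\n",
              if (is.matrix(x$labels)) "per time step" else "per instance",
              if (is.null(x$truth_mask)) "none"
              else sprintf("%d true cells", sum(x$truth_mask))))
  invisible(x)
}

#' Number of instances / time steps / channels of a dataset
#' @param dataset a `ts_dataset`.
#' @return integer.
#' @export
n_instances <- function(dataset) dim(dataset$data)[1L]

#' @rdname n_instances
#' @export
n_steps <- function(dataset) dim(dataset$data)[2L]

#' @rdname n_instances
#' @export
n_channels <- function(dataset) dim(dataset$data)[3L]

# per-instance label vector used for stratified splitting; per-time-step
# labelled datasets are stratified on the modal label of each instance
instance_labels <- function(dataset) {
  if (!is.matrix(dataset$labels)) return(dataset$labels)
  apply(dataset$labels, 1L, function(r) {
    tb <- tabulate(r + 1L, nbins = dataset$n_classes)
    which.max(tb) - 1L
  })
}

#' Slice a dataset to a subset of instances
#' @param dataset a `ts_dataset`.
#' @param idx integer instance indices.
#' @return a `ts_dataset` (class presence is not re-validated on slices).
#' @keywords internal
slice_instances <- function(dataset, idx) {
  out <- dataset
  out$data <- dataset$data[idx, , , drop = FALSE]
  out$labels <- if (is.matrix(dataset$labels))
    dataset$labels[idx, , drop = FALSE] else dataset$labels[idx]
  out
}

#' Cut a dataset into fixed-length sliding windows
#'
#' Each instance of length `t` becomes `floor((t - window) / stride) + 1`
#' windows of length `window`. Per-time-step labels are sliced with the
#' window; per-instance labels are copied to every window. The truth mask is
#' dropped (it refers to absolute time positions of the unwindowed series).
#'
#' @param dataset a `ts_dataset`.
#' @param window window length `t'` (`1 <= window <= t`).
#' @param stride positive step between window starts (default 1).
#' @return a `ts_dataset` of windows; attribute `"source_instance"` maps each
#'   window back to its original instance.
#' @export
window_dataset <- function(dataset, window, stride = 1L) {
  t_len <- n_steps(dataset)
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 1L || window > t_len) stop("window must lie in 1 .. t")
  if (stride < 1L) stop("stride must be positive")
  starts <- seq.int(1L, t_len - window + 1L, by = stride)
  n <- n_instances(dataset); c_len <- n_channels(dataset)
  per_step <- is.matrix(dataset$labels)

  n_win <- n * length(starts)
  out_data <- array(0, dim = c(n_win, window, c_len))
  out_labels <- if (per_step) matrix(0L, n_win, window) else integer(n_win)
  src <- integer(n_win)
  k <- 0L
  for (i in seq_len(n)) {
    for (s0 in starts) {
      k <- k + 1L
      out_data[k, , ] <- dataset$data[i, s0:(s0 + window - 1L), ]
      if (per_step) out_labels[k, ] <- dataset$labels[i, s0:(s0 + window - 1L)]
      else out_labels[k] <- dataset$labels[i]
      src[k] <- i
    }
  }
  out <- ts_dataset(out_data, out_labels, n_classes = dataset$n_classes,
                    channel_names = dataset$channel_names)
  attr(out, "source_instance") <- src
  out
}
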