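# Plain-text serialisation: every artefact is CSV + a JSON sidecar so runs
# are reproducible and diffable without binary formats.

#' Write / read a dataset as delimited text
#'
#' A directory with `meta.json` (dimensions, classes, channel names, label
#' kind), `data.csv` in long format (instance, step, channel, value; all
#' indices 0-based), `labels.csv` and optionally `mask.csv`.
#'
#' @param dataset a [ts_dataset()].
#' @param dir output directory (created if missing).
#' @return `write_dataset` the directory, invisibly; `read_dataset` a
#'   [ts_dataset()].
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(dataset$data)
  meta <- list(n = d[1L], t = d[2L], c = d[3L],
               n_classes = dataset$n_classes,
               channel_names = dataset$channel_names,
               label_kind = if (is.matrix(dataset$labels)) "per_step"
                            else "per_instance",
               has_mask = !is.null(dataset$truth_mask))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  long <- data.frame(
    instance = rep(seq_len(d[1L]) - 1L, times = d[2L] * d[3L]),
    step = rep(rep(seq_len(d[2L]) - 1L, each = d[1L]), times = d[3L]),
    channel = rep(seq_len(d[3L]) - 1L, each = d[1L] * d[2L]),
    value = as.numeric(dataset$data))
  utils::write.csv(long, file.path(dir, "data.csv"), row.names = FALSE)
  if (is.matrix(dataset$labels)) {
    utils::write.csv(as.data.frame(dataset$labels),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  } else {
    utils::write.csv(data.frame(label = dataset$labels),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  }
  if (!is.null(dataset$truth_mask))
    utils::write.csv(as.data.frame(dataset$truth_mask * 1L),
                     file.path(dir, "mask.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  long <- utils::read.csv(file.path(dir, "data.csv"))
  data <- array(0, c(meta$n, meta$t, meta$c))
  data[cbind(long$instance + 1L, long$step + 1L, long$channel + 1L)] <-
    long$value
  labs <- utils::read.csv(file.path(dir, "labels.csv"))
  labels <- if (identical(meta$label_kind, "per_step"))
    as.matrix(labs) else labs$label
  dimnames(labels) <- NULL
  mask <- NULL
  if (isTRUE(meta$has_mask)) {
    mask <- as.matrix(utils::read.csv(file.path(dir, "mask.csv"))) == 1L
    dimnames(mask) <- NULL
  }
  ts_dataset(data, labels, n_classes = meta$n_classes, truth_mask = mask,
             channel_names = meta$channel_names)
}

#' Write / read a gradient archive as delimited text
#'
#' A directory with `meta.json` (mode, shape, and optionally the training
#' config) and `entries.csv` in long format (epoch, batch, step, channel,
#' value; `step` is -1 for channel-vector archives; indices 0-based).
#'
#' @param archive a [gradient_archive()].
#' @param dir output directory.
#' @param config optional [training_config()] stored in the sidecar.
#' @return `write_archive` the directory, invisibly; `read_archive` a
#'   [gradient_archive()].
#' @export
write_archive <- function(archive, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(mode = archive$mode, epochs = archive$epochs,
               batches_per_epoch = archive$batches_per_epoch,
               window_steps = archive$window_steps,
               channels = archive$channels,
               config = if (is.null(config)) NULL else unclass(config))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       null = "null")
  e <- archive$entries
  d <- dim(e)
  if (archive$mode == "channel_vector") {
    long <- data.frame(
      epoch = rep(seq_len(d[1L]) - 1L, times = d[2L] * d[3L]),
      batch = rep(rep(seq_len(d[2L]) - 1L, each = d[1L]), times = d[3L]),
      step = -1L,
      channel = rep(seq_len(d[3L]) - 1L, each = d[1L] * d[2L]),
      value = as.numeric(e))
  } else {
    long <- data.frame(
      epoch = rep(seq_len(d[1L]) - 1L, times = prod(d[-1L])),
      batch = rep(rep(seq_len(d[2L]) - 1L, each = d[1L]),
                  times = d[3L] * d[4L]),
      step = rep(rep(seq_len(d[3L]) - 1L, each = d[1L] * d[2L]),
                 times = d[4L]),
      channel = rep(seq_len(d[4L]) - 1L, each = prod(d[1:3])),
      value = as.numeric(e))
  }
  utils::write.csv(long, file.path(dir, "entries.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_archive
#' @export
read_archive <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  long <- utils::read.csv(file.path(dir, "entries.csv"))
  if (identical(meta$mode, "channel_vector")) {
    e <- array(0, c(meta$epochs, meta$batches_per_epoch, meta$channels))
    e[cbind(long$epoch + 1L, long$batch + 1L, long$channel + 1L)] <- long$value
  } else {
    e <- array(0, c(meta$epochs, meta$batches_per_epoch, meta$window_steps,
                    meta$channels))
    e[cbind(long$epoch + 1L, long$batch + 1L, long$step + 1L,
            long$channel + 1L)] <- long$value
  }
  gradient_archive(e, meta$mode, meta$window_steps, meta$channels)
}

#' Write an importance estimate as delimited text
#'
#' Columns: `feature_id` (0-based), `feature_label`, `method`, `score`,
#' `rank` (1 = most important), `run_seed`.
#'
#' @param est an [importance_estimate()].
#' @param path output CSV path.
#' @param run_seed seed of the run the estimate came from.
#' @return the path, invisibly.
#' @export
write_importance <- function(est, path, run_seed = NA_integer_) {
  rank <- integer(length(est$scores))
  rank[est$ranking] <- seq_along(est$scores)
  df <- data.frame(feature_id = seq_along(est$scores) - 1L,
                   feature_label = est$feature_labels,
                   method = est$method, score = est$scores,
                   rank = rank, run_seed = run_seed)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_importance
#' @export
read_importance <- function(path) {
  utils::read.csv(path)
}

# per-run min-max normalisation to [0,1]; reporting/visualisation only,
# never applied before ranking
normalise01 <- function(x) {
  r <- range(x)
  if (r[1L] == r[2L]) return(rep(0, length(x)))
  (x - r[1L]) / (r[2L] - r[1L])
}
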