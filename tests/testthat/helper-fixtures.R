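# small in-code fixtures shared across test files

# tiny balanced per-instance dataset: n instances, t steps, c channels,
# K classes; data drawn once under `seed` with class-dependent shifts so the
# classes are learnable
tiny_dataset <- function(n = 24, t = 10, c = 2, K = 2, seed = 42,
                         shift = 1) {
  set.seed(seed)
  labels <- rep(seq_len(K) - 1L, length.out = n)
  data <- array(stats::rnorm(n * t * c, 0, 0.1), c(n, t, c))
  for (i in seq_len(n)) data[i, , 1] <- data[i, , 1] + shift * labels[i]
  ts_dataset(data, labels, n_classes = K)
}

# gradient archive with prescribed per-feature batch gradients:
# `per_epoch` is a list over epochs of (batches x features) matrices
archive_from_batches <- function(per_epoch, mode = "channel_vector",
                                 window_steps = 1L) {
  E <- length(per_epoch)
  B <- nrow(per_epoch[[1]])
  f_len <- ncol(per_epoch[[1]])
  if (mode == "channel_vector") {
    e <- array(0, c(E, B, f_len))
    for (ep in seq_len(E)) e[ep, , ] <- per_epoch[[ep]]
    gradient_archive(e, mode, window_steps, f_len)
  } else {
    c_len <- f_len / window_steps
    e <- array(0, c(E, B, window_steps, c_len))
    for (ep in seq_len(E))
      e[ep, , , ] <- array(per_epoch[[ep]], c(B, window_steps, c_len))
    gradient_archive(e, mode, window_steps, c_len)
  }
}

# random archive for property tests
random_archive <- function(E = 4, B = 3, mode = "channel_vector",
                           window_steps = 5, channels = 3, seed = 1) {
  set.seed(seed)
  if (mode == "channel_vector") {
    gradient_archive(array(stats::rnorm(E * B * channels), c(E, B, channels)),
                     mode, window_steps, channels)
  } else {
    gradient_archive(
      array(stats::rnorm(E * B * window_steps * channels),
            c(E, B, window_steps, channels)),
      mode, window_steps, channels)
  }
}

# brute-force reference scorer: recomputes gamma, ROC and trapezoid
# integration from the raw entries with plain loops, independently of the
# analysis code paths
brute_force_grad_scores <- function(archive, method, feature_axis) {
  e <- archive$entries
  E <- archive$epochs; B <- archive$batches_per_epoch
  # feature gradient per (epoch, batch) as a plain matrix of lists
  feat_grad <- function(ep, b) {
    if (archive$mode == "channel_vector") e[ep, b, ]
    else if (feature_axis == "channel") {
      v <- numeric(archive$channels)
      for (j in seq_len(archive$channels))
        v[j] <- sum(e[ep, b, , j])
      v
    } else as.numeric(e[ep, b, , ])
  }
  F_len <- length(feat_grad(1, 1))
  profile <- matrix(0, E, F_len)
  for (ep in seq_len(E)) {
    g <- sapply(seq_len(B), function(b) feat_grad(ep, b))  # F x B
    g <- matrix(g, F_len, B)
    for (f in seq_len(F_len)) {
      profile[ep, f] <- if (method == "grad_std") {
        if (B == 1) 0 else sqrt(sum((g[f, ] - mean(g[f, ]))^2) / (B - 1))
      } else sum(g[f, ])
    }
  }
  trap <- function(v) {
    if (length(v) == 1) return(v)
    s <- 0
    for (i in seq_len(length(v) - 1)) s <- s + (v[i] + v[i + 1]) / 2
    s
  }
  vapply(seq_len(F_len), function(f) {
    v <- profile[, f]
    if (method == "grad_auc") abs(trap(v))
    else if (method == "grad_roc") abs(trap(c(v[1], diff(v))))
    else trap(v)
  }, numeric(1))
}

# closed-form paired t oracle: t = mean(d) / (sd(d) / sqrt(n))
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  list(t = t_stat, p = p, dof = n - 1)
}
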