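test_that("weight-naive scores are absolute magnitudes, ranked descending", {
  ext <- pairwise_extension(4, 3, "channel_vector", trainable = TRUE)
  ext$weights <- c(1.5, -2.0, 0.1)
  est <- weight_naive_scores(ext)
  expect_equal(est$scores, c(1.5, 2.0, 0.1))
  expect_identical(est$ranking, c(2L, 1L, 3L))
  expect_identical(est$feature_axis, "channel")

  # untrained layer: degenerate with warning, index-order tie-break
  ext$weights <- rep(1.0, 3)
  expect_warning(est <- weight_naive_scores(ext), "degenerate")
  expect_identical(est$ranking, 1:3)

  extm <- pairwise_extension(2, 2, "time_channel_matrix", trainable = TRUE)
  extm$weights <- matrix(c(1, 0, -3, 2), 2, 2)  # [[1, -3], [0, 2]]
  est <- weight_naive_scores(extm)
  expect_equal(matrix(est$scores, 2, 2), matrix(c(1, 0, 3, 2), 2, 2))
  expect_identical(est$feature_axis, "time_channel_cell")
})

test_that("profiles aggregate per-epoch batch gradients by sum or std", {
  # one feature; epoch 1 batches (1, 2), epoch 2 batches (3, -1)
  arch <- archive_from_batches(list(matrix(c(1, 2), 2, 1),
                                    matrix(c(3, -1), 2, 1)))
  expect_equal(build_profile(arch, "sum", "channel")$values[, 1], c(3, 2))
  expect_equal(build_profile(arch, "std", "channel")$values[, 1],
               c(sd(c(1, 2)), sd(c(3, -1))))  # ddof 1: 0.7071..., 2.8284...
  expect_equal(build_profile(arch, "std", "channel")$values[, 1],
               c(0.70710678, 2.82842712), tolerance = 1e-7)

  zero <- archive_from_batches(list(matrix(0, 3, 2), matrix(0, 3, 2)))
  expect_true(all(build_profile(zero, "sum", "channel")$values == 0))

  # single batch per epoch: std profile is zero, with warning
  single <- archive_from_batches(list(matrix(5, 1, 1), matrix(2, 1, 1)))
  expect_warning(p <- build_profile(single, "std", "channel"), "single batch")
  expect_true(all(p$values == 0))

  # matrix-mode archive reduced to channels: gradients summed over time first
  set.seed(3)
  e <- array(rnorm(2 * 3 * 4 * 2), c(2, 3, 4, 2))
  arch_m <- gradient_archive(e, "time_channel_matrix", 4, 2)
  p <- build_profile(arch_m, "sum", "channel")
  manual <- sapply(1:2, function(j) sapply(1:2, function(ep)
    sum(e[ep, , , j])))
  expect_equal(p$values, manual, tolerance = 1e-12)
  expect_error(build_profile(arch_m, "sum", "time_step"), "single-channel")
})

test_that("profile_auc is the unit-spaced trapezoid rule", {
  for (E in c(2, 5, 9)) expect_equal(profile_auc(rep(3.5, E)), 3.5 * (E - 1))
  expect_equal(profile_auc(numeric(3)), 0)
  expect_equal(profile_auc(c(0, 2, 0)), 2)
  expect_equal(profile_auc(7), 7)  # single epoch returns the value
  expect_error(profile_auc(numeric(0)), "empty")

  # linearity: auc(a v + b w) = a auc(v) + b auc(w)
  set.seed(8)
  for (i in 1:20) {
    v <- rnorm(6); w <- rnorm(6); a <- rnorm(1); b <- rnorm(1)
    expect_equal(profile_auc(a * v + b * w),
                 a * profile_auc(v) + b * profile_auc(w), tolerance = 1e-12)
  }
})

test_that("profile_roc keeps the first value then first-differences", {
  expect_equal(profile_roc(rep(4, 5)), c(4, 0, 0, 0, 0))
  expect_equal(profile_roc(c(1, 3, 2)), c(1, 2, -1))
  expect_equal(profile_roc(numeric(4)), numeric(4))
  expect_error(profile_roc(5), "at least 2")

  # telescoping: sum(roc(v)) == v_E
  set.seed(4)
  for (i in 1:20) {
    v <- rnorm(sample(2:10, 1))
    expect_equal(sum(profile_roc(v)), v[length(v)], tolerance = 1e-12)
  }
})

test_that("grad scores match the constant-profile closed form", {
  # feature A: per-epoch sums (2,2,2); feature B: zeros; E = 3
  arch <- archive_from_batches(list(matrix(c(1, 1, 0, 0), 2, 2),
                                    matrix(c(2, 0, 0, 0), 2, 2),
                                    matrix(c(0.5, 1.5, 0, 0), 2, 2)))
  est <- grad_scores(arch, "grad_auc", "channel")
  expect_equal(est$scores, c(4, 0))
  expect_identical(est$ranking, c(1L, 2L))

  # all features identical: equal scores, index-order ranking
  sym <- archive_from_batches(list(matrix(1, 2, 3), matrix(2, 2, 3)))
  for (m in c("grad_auc", "grad_roc", "grad_std")) {
    est <- grad_scores(sym, m, "channel")
    expect_true(all(est$scores == est$scores[1]))
    expect_identical(est$ranking, 1:3)
  }
})

test_that("grad scores equal an independent brute-force recomputation", {
  cases <- list(
    list(mode = "channel_vector", axis = "channel"),
    list(mode = "time_channel_matrix", axis = "channel"),
    list(mode = "time_channel_matrix", axis = "time_channel_cell"))
  for (cs in cases) for (m in c("grad_auc", "grad_roc", "grad_std")) {
    arch <- random_archive(E = 5, B = 4, mode = cs$mode, window_steps = 3,
                           channels = 2, seed = 17)
    est <- grad_scores(arch, m, cs$axis)
    oracle <- brute_force_grad_scores(arch, m, cs$axis)
    expect_equal(est$scores, oracle, tolerance = 1e-12)
    # validity: descending along the ranking, bijective
    expect_true(all(diff(est$scores[est$ranking]) <= 0))
    expect_identical(sort(est$ranking), seq_along(est$scores))
  }
})

test_that("grad_std scores are non-negative without absolute values", {
  arch <- random_archive(E = 6, B = 5, seed = 23)
  arch$entries <- -abs(arch$entries)  # all-negative gradients
  expect_true(all(grad_scores(arch, "grad_std", "channel")$scores >= 0))
})

test_that("permuting archive features permutes scores and ranking", {
  arch <- random_archive(E = 4, B = 3, channels = 4, seed = 31)
  perm <- c(3L, 1L, 4L, 2L)
  arch_p <- gradient_archive(arch$entries[, , perm], "channel_vector",
                             arch$window_steps, 4)
  for (m in c("grad_auc", "grad_roc", "grad_std")) {
    a <- grad_scores(arch, m, "channel")
    b <- grad_scores(arch_p, m, "channel")
    expect_equal(b$scores, a$scores[perm], tolerance = 1e-12)
    expect_identical(perm[b$ranking], a$ranking)
  }
})

test_that("AHP aggregation is the column mean of cell scores", {
  est <- importance_estimate(c(1, 3, 0, 0), "grad_auc", "time_channel_cell",
                             dims = c(2L, 2L))  # cells [[1, 0], [3, 0]]
  agg <- ahp_aggregate(est)
  expect_equal(agg$scores, c(2, 0))
  expect_identical(agg$ranking, c(1L, 2L))
  expect_identical(agg$feature_axis, "channel")

  # uniform cells: equal channel scores, index-order ranking
  u <- ahp_aggregate(importance_estimate(rep(2, 6), "grad_auc",
                                         "time_channel_cell",
                                         dims = c(2L, 3L)))
  expect_true(all(u$scores == 2))
  expect_identical(u$ranking, 1:3)

  # scaling one channel's cells by k scales its aggregate by k
  sc <- c(1, 3, 0.5, 2)
  base <- ahp_aggregate(importance_estimate(sc, "grad_auc",
                                            "time_channel_cell",
                                            dims = c(2L, 2L)))
  k <- 7
  scaled <- ahp_aggregate(importance_estimate(c(sc[1:2] * k, sc[3:4]),
                                              "grad_auc", "time_channel_cell",
                                              dims = c(2L, 2L)))
  expect_equal(scaled$scores[1], k * base$scores[1])
  expect_equal(scaled$scores[2], base$scores[2])

  expect_error(ahp_aggregate(importance_estimate(1:5, "grad_auc",
                                                 "time_channel_cell",
                                                 dims = c(2L, 2L))),
               "reshape")
})
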