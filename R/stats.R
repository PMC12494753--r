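#' Weighted and per-class F1 scores
#'
#' Standard harmonic mean of precision and recall per class, averaged with
#' weights proportional to class support in `labels`. Per-time-step
#' predictions should be flattened before calling. A class with no true
#' instances (or with an undefined precision/recall) contributes an F1 of 0,
#' with a warning when a declared class is absent from the labels.
#'
#' @param predictions integer vector of predicted classes (0-based).
#' @param labels integer vector of true classes (0-based), same length.
#' @param classes number of classes `K`.
#' @return list with `weighted` (scalar) and `per_class` (length-K vector).
#' @export
f1_scores <- function(predictions, labels, classes) {
  predictions <- as.integer(predictions); labels <- as.integer(labels)
  if (!length(labels)) stop("empty input")
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  classes <- as.integer(classes)
  per_class <- numeric(classes)
  support <- numeric(classes)
  for (k in seq_len(classes) - 1L) {
    tp <- sum(predictions == k & labels == k)
    fp <- sum(predictions == k & labels != k)
    fn <- sum(predictions != k & labels == k)
    support[k + 1L] <- tp + fn
    per_class[k + 1L] <- if (2 * tp + fp + fn == 0) 0
                         else 2 * tp / (2 * tp + fp + fn)
  }
  if (any(support == 0))
    warning("class(es) absent from labels get F1 = 0: ",
            paste(which(support == 0) - 1L, collapse = ", "))
  weighted <- if (sum(support) == 0) 0
              else sum(per_class * support) / sum(support)
  list(weighted = weighted, per_class = per_class)
}

#' Paired comparison of two per-run score sequences
#'
#' Compares two equal-length sequences of per-run scores (e.g. F1 over
#' repeat runs). A paired t-test is used when the two sequences have similar
#' spread, defined by `1/2 < sd(a)/sd(b) < 2` (sample standard deviations of
#' the score sequences themselves, not of the differences); otherwise
#' Welch's two-sample t-test is used. p-values are two-sided. The Bonferroni
#' threshold `0.05 / n_comparisons` is attached; Holm-adjusted p-values for
#' a whole family of comparisons come from [holm_adjust()].
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @param n_comparisons size of the comparison family for the Bonferroni
#'   threshold (default 1).
#' @return an object of class `"paired_comparison"` with fields `t_stat`,
#'   `dof`, `p_value`, `test_used`, `alpha_bonferroni`, `p_holm` (NA until
#'   set by a family-level adjustment).
#' @export
paired_compare <- function(a, b, n_comparisons = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("paired comparison needs at least 2 runs")
  if (all(a == b)) {
    # identical sequences carry no evidence of a difference: t = 0, p = 1
    return(structure(list(a = a, b = b, t_stat = 0, dof = length(a) - 1L,
                          p_value = 1, test_used = "paired",
                          alpha_bonferroni = 0.05 / n_comparisons,
                          p_holm = NA_real_),
                     class = "paired_comparison"))
  }
  sd_a <- stats::sd(a); sd_b <- stats::sd(b)
  ratio <- if (sd_b == 0) Inf else sd_a / sd_b
  use_paired <- is.finite(ratio) && ratio > 0.5 && ratio < 2
  if (use_paired) {
    d <- a - b
    if (stats::sd(d) == 0) {
      # a constant non-zero difference has an undefined (infinite) t
      stop("zero variance of paired differences; test refused",
           call. = FALSE)
    }
    tt <- stats::t.test(a, b, paired = TRUE)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
  }
  structure(list(a = a, b = b,
                 t_stat = unname(tt$statistic),
                 dof = unname(tt$parameter),
                 p_value = unname(tt$p.value),
                 test_used = if (use_paired) "paired" else "welch",
                 alpha_bonferroni = 0.05 / n_comparisons,
                 p_holm = NA_real_),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s t = %.4g, dof = %.3g, p = %.4g%s\n",
              x$test_used, x$t_stat, x$dof, x$p_value,
              if (is.na(x$p_holm)) "" else sprintf(", holm p = %.4g", x$p_holm)))
  invisible(x)
}

#' Holm step-down adjustment of p-values
#'
#' The classic step-down multiple-testing correction: sort ascending,
#' multiply the i-th smallest by (n - i + 1), enforce monotonicity with a
#' running maximum, cap at 1, and restore the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  p <- as.numeric(p)
  if (!length(p)) return(p)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1L) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Family of paired comparisons with multiplicity control
#'
#' Runs [paired_compare()] for every named pair against a common baseline,
#' attaches the family-wide Bonferroni threshold and Holm-adjusted p-values.
#'
#' @param baseline numeric per-run scores of the reference method.
#' @param others named list of per-run score vectors.
#' @return named list of `paired_comparison` objects with `p_holm` filled in.
#' @export
compare_family <- function(baseline, others) {
  n <- length(others)
  cmps <- lapply(others, function(s) paired_compare(s, baseline, n))
  ph <- holm_adjust(vapply(cmps, `[[`, numeric(1), "p_value"))
  for (i in seq_along(cmps)) cmps[[i]]$p_holm <- ph[[i]]
  cmps
}
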