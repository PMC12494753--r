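#' Specification of a synthetic benchmark dataset
#'
#' Describes one of the four packaged three-class benchmarks. All four share
#' the same stated world: 300 instances per class, 1000 time steps, additive
#' Gaussian noise with mean 0 and standard deviation 0.02.
#'
#' * `uni_peaks`   - univariate; classes differ by the period in which a
#'   smooth unit-amplitude bump occurs (defaults: windows centred at 20%,
#'   50% and 80% of the series, each 10% of the series wide).
#' * `uni_patterns` - univariate; classes differ by waveform (sine, square,
#'   triangle) over a common active region.
#' * `multi_0`     - 3 channels; channel 1 (`ch0`) is pure noise for every
#'   class, channel 2 carries a class-specific bump, channel 3 carries a bump
#'   for class 2 only.
#' * `multi_1`     - 3 channels; `ch0` is pure noise, classes 0 and 1 are
#'   distinguished by opposite-phase sine bursts in channel 2, class 2 by a
#'   bump in channel 3 only (its channel-2 template equals class 0's, so
#'   class 2 differs from class 0 in channel 3 alone).
#'
#' @param kind one of `"uni_peaks"`, `"uni_patterns"`, `"multi_0"`,
#'   `"multi_1"`.
#' @param samples_per_class instances per class (default 300).
#' @param time_steps series length (default 1000).
#' @param noise_sd Gaussian noise standard deviation (default 0.02).
#' @param seed RNG seed.
#' @param class_params optional list overriding per-kind pattern parameters;
#'   see Details in the generator help pages.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(kind = c("uni_peaks", "uni_patterns",
                                    "multi_0", "multi_1"),
                           samples_per_class = 300L, time_steps = 1000L,
                           noise_sd = 0.02, seed = 1L, class_params = list()) {
  kind <- match.arg(kind)
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (samples_per_class < 1L || time_steps < 1L)
    stop("samples_per_class and time_steps must be positive")
  structure(list(kind = kind,
                 samples_per_class = as.integer(samples_per_class),
                 time_steps = as.integer(time_steps),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 class_params = class_params),
            class = "synthetic_spec")
}

# smooth unit-amplitude bump (Hann window) of `width` steps placed at
# `centre` (fraction of t) inside a zero vector of length t
hann_bump <- function(t_len, centre_frac, width, amplitude = 1) {
  v <- numeric(t_len)
  w <- max(2L, as.integer(width))
  start <- max(1L, round(centre_frac * t_len - w / 2))
  end <- min(t_len, start + w - 1L)
  idx <- start:end
  v[idx] <- amplitude * 0.5 * (1 - cos(2 * pi * (seq_along(idx) - 1) /
                                         (length(idx) - 1)))
  v
}

# assemble dataset from per-class template array (K x t x c)
templates_to_dataset <- function(templates, spec, truth_mask,
                                 channel_names = NULL) {
  K <- dim(templates)[1L]; t_len <- dim(templates)[2L]
  c_len <- dim(templates)[3L]
  n <- K * spec$samples_per_class
  set.seed(spec$seed)
  data <- array(0, dim = c(n, t_len, c_len))
  labels <- rep(seq_len(K) - 1L, each = spec$samples_per_class)
  for (i in seq_len(n)) {
    tpl <- templates[labels[i] + 1L, , ]
    data[i, , ] <- tpl + stats::rnorm(t_len * c_len, 0, spec$noise_sd)
  }
  out <- ts_dataset(data, labels, n_classes = K, truth_mask = truth_mask,
                    channel_names = channel_names)
  attr(out, "templates") <- templates
  attr(out, "spec") <- spec
  out
}

#' Generate the univariate peak-period benchmark
#'
#' Each class places a smooth unit-amplitude bump in a class-specific,
#' non-overlapping window; the baseline is zero elsewhere. The ground-truth
#' mask marks the union of the three windows.
#'
#' `class_params` may override `centres` (fractions of t, default
#' `c(0.2, 0.5, 0.8)`), `width_frac` (default 0.1) and `amplitude`
#' (default 1).
#'
#' @param spec a `synthetic_spec` with `kind = "uni_peaks"`.
#' @return a `ts_dataset` with per-instance labels, a `t x 1` truth mask and
#'   an attached `"templates"` attribute (K x t x 1 noiseless class means).
#' @export
gen_univariate_peaks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$kind != "uni_peaks") stop("spec kind must be 'uni_peaks'")
  p <- utils::modifyList(list(centres = c(0.2, 0.5, 0.8), width_frac = 0.1,
                              amplitude = 1), spec$class_params)
  t_len <- spec$time_steps
  w <- round(p$width_frac * t_len)
  K <- length(p$centres)
  # reject overlapping class windows
  starts <- round(p$centres * t_len - w / 2)
  ends <- starts + w - 1L
  o <- order(starts)
  if (any(starts[o][-1L] <= ends[o][-K]))
    stop("class peak windows overlap; choose more separated centres")

  templates <- array(0, dim = c(K, t_len, 1L))
  mask <- matrix(FALSE, t_len, 1L)
  for (k in seq_len(K)) {
    bump <- hann_bump(t_len, p$centres[k], w, p$amplitude)
    templates[k, , 1L] <- bump
    mask[bump > 0, 1L] <- TRUE
  }
  templates_to_dataset(templates, spec, mask)
}

# one period of each supported waveform, amplitude 1
waveform_value <- function(name, phase) {
  switch(name,
         sine = sin(2 * pi * phase),
         square = ifelse(sin(2 * pi * phase) >= 0, 1, -1),
         triangle = 4 * abs(phase - floor(phase + 0.5)) - 1,
         stop("unknown waveform: ", name))
}

#' Generate the univariate signal-format benchmark
#'
#' Each class uses a distinct waveform (defaults: sine, square, triangle at a
#' common frequency of 5 cycles over the series) over the whole series. The
#' ground-truth mask marks steps where any two class templates differ by more
#' than the noise standard deviation.
#'
#' `class_params` may override `waveforms` (character, default
#' `c("sine","square","triangle")`), `cycles` (default 5) and `amplitude`
#' (default 1).
#'
#' @param spec a `synthetic_spec` with `kind = "uni_patterns"`.
#' @return a `ts_dataset`; see [gen_univariate_peaks()] for attributes.
#' @export
gen_univariate_patterns <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$kind != "uni_patterns") stop("spec kind must be 'uni_patterns'")
  p <- utils::modifyList(list(waveforms = c("sine", "square", "triangle"),
                              cycles = 5, amplitude = 1), spec$class_params)
  if (anyDuplicated(p$waveforms))
    stop("class waveforms must be distinct")
  if (p$amplitude == 0)
    stop("zero-amplitude waveforms make the classes indistinguishable")
  t_len <- spec$time_steps
  K <- length(p$waveforms)
  phase <- (seq_len(t_len) - 1) / t_len * p$cycles
  templates <- array(0, dim = c(K, t_len, 1L))
  for (k in seq_len(K))
    templates[k, , 1L] <- p$amplitude * waveform_value(p$waveforms[k], phase)
  # important steps: any pair of class templates separated by > noise_sd
  sep <- matrix(FALSE, t_len, 1L)
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K)
    sep[abs(templates[i, , 1L] - templates[j, , 1L]) > spec$noise_sd, 1L] <- TRUE
  if (!any(sep)) stop("class templates are indistinguishable at this noise level")
  templates_to_dataset(templates, spec, sep)
}

#' Generate the multivariate benchmarks with a noise channel
#'
#' Both variants have 3 channels and channel `ch0` carries pure noise for
#' every class; its truth-mask column is entirely `FALSE`.
#'
#' `multi_0`: channel `ch1` carries a class-specific bump (centres 20%, 50%,
#' 80% of the series), channel `ch2` carries a bump for class 2 only, so
#' `ch1` separates all three classes and strictly dominates the mask.
#'
#' `multi_1`: classes 0 and 1 are distinguished by opposite-phase sine bursts
#' in `ch1` (class 2 shares class 0's burst), class 2 is marked by a bump in
#' `ch2` only.
#'
#' @param spec a `synthetic_spec` with `kind` `"multi_0"` or `"multi_1"`.
#' @return a `ts_dataset` with 3 channels named `"ch0","ch1","ch2"`.
#' @export
gen_multivariate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!spec$kind %in% c("multi_0", "multi_1"))
    stop("spec kind must be 'multi_0' or 'multi_1'")
  p <- utils::modifyList(list(channels = 3L, centres = c(0.2, 0.5, 0.8),
                              width_frac = 0.1, amplitude = 1,
                              burst_window = c(0.3, 0.7), burst_cycles = 4),
                         spec$class_params)
  if (p$channels < 3L) stop("the multivariate benchmarks need at least 3 channels")
  t_len <- spec$time_steps
  K <- 3L
  templates <- array(0, dim = c(K, t_len, p$channels))
  mask <- matrix(FALSE, t_len, p$channels)
  w <- round(p$width_frac * t_len)

  if (spec$kind == "multi_0") {
    for (k in seq_len(K)) {
      bump <- hann_bump(t_len, p$centres[k], w, p$amplitude)
      templates[k, , 2L] <- bump
      mask[bump > 0, 2L] <- TRUE
    }
    bump2 <- hann_bump(t_len, 0.5, w, p$amplitude)
    templates[3L, , 3L] <- bump2
    mask[bump2 > 0, 3L] <- TRUE
  } else {
    idx <- seq.int(round(p$burst_window[1L] * t_len),
                   round(p$burst_window[2L] * t_len))
    phase <- (seq_along(idx) - 1) / length(idx) * p$burst_cycles
    burst <- p$amplitude * sin(2 * pi * phase)
    templates[1L, idx, 2L] <- burst          # class 0
    templates[2L, idx, 2L] <- -burst         # class 1: opposite phase
    templates[3L, idx, 2L] <- burst          # class 2 shares class 0's ch1
    mask[idx, 2L] <- TRUE
    bump2 <- hann_bump(t_len, 0.5, w, p$amplitude)
    templates[3L, , 3L] <- bump2             # class 2 marker
    mask[bump2 > 0, 3L] <- TRUE
  }
  templates_to_dataset(templates, spec, mask,
                       channel_names = paste0("ch", seq_len(p$channels) - 1L))
}

#' Generate any of the packaged benchmarks from its spec
#' @param spec a `synthetic_spec`.
#' @return a `ts_dataset`.
#' @export
gen_synthetic <- function(spec) {
  switch(spec$kind,
         uni_peaks = gen_univariate_peaks(spec),
         uni_patterns = gen_univariate_patterns(spec),
         gen_multivariate(spec))
}
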