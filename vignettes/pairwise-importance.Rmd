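---
title: "Estimating time-series feature importance from an embedded pairwise layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating time-series feature importance from an embedded pairwise layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairwiseIE)
```

## The model

Neural time-series classifiers select features internally, but that
selection is hidden behind non-linearities. This package makes it
observable by inserting a *pairwise layer* between the input and the host
network: a diagonal linear map with exactly one weight per input entry,
applied by element-wise multiplication, so the classification pipeline is

$$ f(x) \;=\; \mathrm{NN}(x \odot P). $$

Every weight is initialised to exactly 1.0 — the layer starts as the
identity, all features share a common reference point, and the host model's
forward pass is unchanged. This is deliberately *not* a general linear
layer: with one weight per entry, the gradient of the loss with respect to
a pairwise weight is attributable to a single input feature, which is what
makes the analysis below interpretable.

For a multivariate window of shape $t' \times c$ there are two layer
shapes:

* **Channel vector (EWM)** — one weight per channel, shared over time:
  $x \odot C$, $C \in \mathbb{R}^c$. Yields channel importance directly.
* **Time–channel matrix (Hadamard product)** — a full $t' \times c$ weight
  matrix: $x \odot P$. Yields per-(time step, channel) cell importance;
  cell scores are reduced to channel scores by averaging along the time
  axis (*aggregated Hadamard product*, `ahp_aggregate()`).

A third conceivable shape — one weight per time step shared across
channels — is intentionally unsupported: it cannot distinguish the time
steps of different channels, so its estimates are unrepresentative.

## Two estimation modes

**Weight profiles** (`trainable = TRUE`): the layer trains jointly with the
host model under the same optimiser; importance is the absolute magnitude
of the final weights (`weight_naive_scores()`). Simple, but it perturbs the
model it is meant to explain and is noise-prone; it serves as a baseline.

**Gradient profiles** (`trainable = FALSE`, the default): the layer is
*immutable* — gradients of its weights are computed every batch but the
update step is suppressed, so the layer stays the identity and the host
model trains exactly as if the layer were absent. A gradient-collection
module archives $g^f_{e,b}$, the optimiser-visible gradient of the
mean-reduced batch loss for every weight, batch and epoch, captured before
any optimiser-state transformation (this is the quantity that would have
driven the weight, which is why we archive it rather than a
post-transform value). The per-feature *gradient profile* is
$G^f = (\gamma(g^f_1), \ldots, \gamma(g^f_E))$ with $\gamma$ either the
within-epoch sum or the across-batch sample standard deviation, and three
scores are derived:

| method | score | $\gamma$ |
|---|---|---|
| Grad-AUC | $\lvert \mathrm{AUC}(G^f) \rvert$ | sum |
| Grad-ROC | $\lvert \mathrm{AUC}(\mathrm{ROC}(G^f)) \rvert$ | sum |
| Grad-STD | $\mathrm{AUC}(G^f)$ | sd (non-negative, no $\lvert\cdot\rvert$) |

Rankings sort scores descending with ties broken by ascending feature
index (stable and reproducible).

## Numerical choices

* **AUC rule.** "Area under curve" over a discrete epoch profile is read as
  the trapezoid rule with unit spacing; a single-epoch profile returns its
  value. Trapezoid AUC is linear, which the tests exploit as an invariant.
* **ROC sequence.** The rate-of-change of a profile is implemented as
  $(v_1, v_2 - v_1, \ldots, v_E - v_{E-1})$: first value retained, then
  consecutive differences, so the plain sum telescopes back to $v_E$. The
  published formula for this sequence skips the second difference and
  indexes epochs inconsistently; we read both as typographical slips, since
  the stated intent is "the AUC of the derivative" of the profile.
* **Epoch aggregation for STD** uses the sample convention (divisor
  $B - 1$); an epoch with a single batch contributes 0, with a warning.
* **Matrix-to-channel reduction.** When channel profiles are requested from
  a matrix-mode archive, cell gradients are summed over time *before*
  $\gamma$. This is exact, not a convention: the gradient of a
  channel-shared weight is mathematically the time-sum of the cell
  gradients (the tests verify the two routes coincide).
* **AHP aggregation** uses the mean over time (the sum gives identical
  rankings; the mean keeps scales comparable across window lengths).
* **Degenerate inputs.** An all-ones layer passed to
  `weight_naive_scores()` warns (degenerate ranking); min–max
  normalisation to $[0,1]$ is applied only when writing report heatmaps,
  never before ranking.

## Host models and training

No deep-learning framework is assumed: the two reference hosts are
implemented with hand-derived gradients, which also gives the pairwise
layer *exact* archived gradients (checked against finite differences at
relative tolerance $10^{-4}$).

* `shallow_softmax_classifier()` — flatten, one linear layer, softmax; the
  benchmark host. Glorot-uniform init by default; `init_scale` forces a
  constant (channel-symmetric) init, under which channel-permutation
  equivariance of the whole training trajectory is exact — with random
  per-feature init the property holds only in distribution, which is why
  the equivariance test pins the init.
* `lstm_per_step_classifier()` — single LSTM layer, optional dropout,
  per-time-step softmax ($t' \times K$ output), full BPTT including
  $\partial L / \partial x$ (the quantity the pairwise layer consumes).
  Reference shapes: hidden 2 / dropout 0.2 (occupancy-style windows of 64),
  hidden 64 (activity-recognition-style windows). A compact convolutional
  EEG host is recorded as a configuration stub
  (`eegnet_reference_config()`) only — exercising it needs external EEG
  recordings.

Training: Adam (default, lr 0.001) or RMSprop, cross-entropy averaged over
the batch (and time steps for per-step labels), stratified 70/30 split.
One seed drives init, split and batch shuffling; `runs` (default 5)
repeats with consecutive seeds, mirroring the five-runs-with-different-
splits design. Epoch count for the simulated benchmarks is not prescribed
by the source; the default is 100. Batch size is likewise unstated; 32 is
used as the conventional default for datasets of this size (900
instances). The window length is fixed at construction; longer series are
pre-windowed with `window_dataset()` (stride default 1).

## The synthetic world

Four three-class benchmarks, each 300 instances per class, 1000 time
steps, additive Gaussian noise of mean 0 and *standard deviation* 0.02
(the source writes $\mathcal{N}(0, 0.02)$; we read the second parameter as
an sd, consistent with the visible noise scale of its figures):

* `uni_peaks` — classes differ by the period of a smooth unit bump
  (Hann windows centred at 20/50/80% of the series, width 10%); the truth
  mask is the union of the windows.
* `uni_patterns` — classes differ by waveform (sine/square/triangle, 5
  cycles); the mask marks steps where any two templates differ by more
  than the noise sd.
* `multi_0` — 3 channels; `ch0` pure noise, `ch1` a class-specific bump
  (so it separates all classes and dominates the mask), `ch2` a bump for
  class 2 only.
* `multi_1` — `ch0` pure noise; classes 0/1 distinguished by
  opposite-phase sine bursts in `ch1`; class 2 marked by a bump in `ch2`,
  with its `ch1` template shared with class 0 so that class 2 differs from
  class 0 in `ch2` alone. (No assignment can make class 2 differ from
  *both* other classes only in `ch2` while classes 0 and 1 differ in
  `ch1`; sharing class 0's burst is the closest consistent reading.)

The exact curve shapes of the original benchmarks are published only as
figures; the generators parameterise the stated structure (peak periods,
distinct waveforms, noise channel, per-class channel focus) rather than
reproduce pixels, and all verification is against the generated mask, not
the curves. What a green test establishes: that the estimators recover
*this* kind of planted, linearly separable, low-noise structure under a
well-fitting host model. What it does not establish: behaviour on
correlated noise, non-stationarity, class imbalance, or hosts with poor
fit — importance estimates are only as good as the model they observe.

## Verification harness

`run_ablation()` retrains the host from scratch on every Leave-One-Out and
Singleton channel subset ($2\,c\,\cdot$ `runs` retrains; the cost the
protocol is known for), averages weighted validation F1 over runs, and
reports the argmin-LOO and argmax-Singleton channels — which coincide when
one channel dominates the ground truth. Each retrain re-splits with its
own seed (the alternative of freezing one split would entangle the
subsets' comparison with one split's idiosyncrasies). A diverging retrain
is recorded as missing with a warning. Chance-level reference F1, when
needed, is estimated empirically from label-permuted data rather than a
closed form (weighted F1 under imbalance has none).

`architecture_ablation()` compares baseline, trainable-layer and
immutable-layer models over matched seeds: the immutable differences are
exactly zero by construction, and the trainable comparison is attached to
a paired test.

## Comparison statistics

Weighted/per-class F1; paired t-test switching to Welch's test when the
two score sequences' sample sds differ by more than a factor 2
(`paired_compare()`); Bonferroni threshold $0.05/n$ and Holm step-down
adjustment (`holm_adjust()`, `compare_family()`). p-values are two-sided
(the conservative choice; the source does not state sidedness). Two edge
cases are pinned deliberately: identical sequences return the trivial
no-difference result $t = 0, p = 1$, while a *constant non-zero*
difference (zero-variance differences, infinite t) refuses the test with
an error rather than reporting nonsense.

## Known limitations

* Importance is model-relative: it reflects what this host, at this fit
  quality, relied on — not an objective property of the data.
* The dense archive costs $E \cdot B \cdot t' \cdot c$ doubles in memory
  (48 MB for the matrix-mode benchmark runs here); very long runs should
  be serialised in chunks via `write_archive()`.
* Matrix-mode estimates on windowed data describe window positions, not
  absolute time.
* The R implementation is single-threaded by design — determinism under a
  fixed seed is part of the contract.
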