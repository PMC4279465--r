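---
title: "Detecting and identifying foreign matter in transfusion-bottle image sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and identifying foreign matter in transfusion-bottle image sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inspection problem

Sealed liquid pharmaceuticals must be free of visible particulate
contamination — rubber fragments from stoppers, hairs, floating debris.
Automated inspection lines spin the bottle, stop it abruptly, and image
the still-swirling liquid: the container surface (embossing, labels,
scratches) is now static while any suspended particle keeps moving with
the vortex. Air bubbles also move, and they are the main benign
confounder: a bottle whose only moving objects are bubbles is a
qualified product. The task is therefore two-stage — *detect* moving
objects against a complex static background, then *identify* each one as
rubber, hair, debris or bubble.

`fminspect` implements that chain for 8-bit grayscale frame sequences:

1. a per-pixel Gaussian-mixture background model that emits a foreground
   mask per frame;
2. connected-component labeling plus a fifteen-feature descriptor per
   blob (six gray-histogram statistics, area, bounding-rectangle side
   ratio, seven Hu moment invariants);
3. multi-class ReliefF feature weighting and ranked-subspace selection;
4. a three-layer sigmoid perceptron classifier whose initial weights and
   thresholds are found by the Mind Evolutionary Algorithm (MEA) and
   fine-tuned by backpropagation (BP);
5. a per-sequence qualified/unqualified verdict.

A synthetic-scene generator provides frame sequences with exact ground
truth, so every stage is testable without inspection-line footage.

## The background model

Each pixel's gray value over time is a mixture of `K = 3` Gaussians with
weights $w_i$, means $u_i$ and variances $\sigma_i^2$ (single channel,
so the general covariance collapses to a scalar). An observation $X_t$
*matches* component $i$ when $|X_t - u_i| < \varphi\,\sigma_i$ with
$\varphi = 2.5$; the inequality is strict. Components are ranked by
$w_i/\sigma_i$ — background modes are both probable and tight — and the
background is the smallest prefix of the ranking whose cumulative weight
strictly exceeds $T_R = 0.25$. A pixel is declared foreground when no
component matches, or when its first matching component (in rank order)
lies below that prefix; both the match and the prefix are evaluated on
the *pre-update* state, and all pixels are then updated.

The update is the standard adaptive-mixture form. On a match with
learning rate $\alpha = 0.05$:

$$w_i \leftarrow (1-\alpha) w_i + \alpha, \qquad
  u \leftarrow (1-\rho) u + \rho X_t, \qquad
  \sigma^2 \leftarrow (1-\rho)\sigma^2 + \rho (X_t - u_{\mathrm{new}})^2$$

with $\rho = \alpha$ fixed rather than scaled by the component
likelihood; the constant-$\rho$ variant is deterministic, cheap, and
converges geometrically (a step change in a pixel's background gray is
re-absorbed in roughly 25 frames at these defaults, a bound the tests
measure with an independent transcription of the rules). Non-matching
components decay by $(1-\alpha)$; if nothing matches, the
lowest-weight component (empty slots first) is replaced by a fresh
component centered at $X_t$ with weight 0.05 before renormalization —
new evidence starts improbable. Weights are renormalized to sum to one
after every update and components re-sorted stably.

Numerical choices worth knowing:

* **Initial spread.** Fresh components get standard deviation 15 gray
  levels ($\sigma^2 = 225$). The scale parameter is read as a standard
  deviation; `gmm_params(variance_is_sigma2 = TRUE)` switches to reading
  it as a variance for sensitivity checks.
* **Variance floor.** $\sigma^2 \ge 4$ at all times, so constant pixels
  cannot collapse the match band or the rank key to a division by zero.
* **Warm start.** The model initializes from the first frame alone
  (component one per pixel at the observed gray, weight one, remaining
  slots empty); the first mask is all-background by construction and
  the pipeline excludes the first five frames from blob harvesting.

## Blob descriptors

Foreground masks are labeled by flood fill (8-connectivity by default;
4 available), blobs under 4 pixels are discarded, and ids follow raster
order. Coordinates are 0-based with row = y and column = x. Each blob
yields, in fixed order:

| features | definition | units |
|---|---|---|
| f01–f06 | mean, variance, relative smoothness $R = 1 - 1/(1+\sigma^2)$, third moment, uniformity $\sum p(k)^2$, entropy $-\sum p(k)\log_2 p(k)$ of the normalized gray histogram over blob member pixels only | gray, gray², –, gray³, –, bits |
| f07 | area (pixel count) | pixels |
| f08 | bounding-rectangle side ratio $W/L$ | – |
| f09–f15 | Hu invariants $H_1 \dots H_7$ | – |

Two deliberate deviations from the naive formulas: the bounding-box
extents use the inclusive $\max - \min + 1$ correction so one-pixel-wide
shapes (hairs) get a finite ratio while rasterized disks still score
exactly 1, and the Hu moments are computed on the *binary silhouette*
rather than gray-weighted — they are used as shape descriptors robust to
the deformation of soft matter, and gray information is already carried
by f01–f06 (`gray_weighted = TRUE` switches this). Central moments are
scale-normalized as $\eta_{pq} = \mu_{pq} / \mu_{00}^{(p+q)/2+1}$, which
the translation/rotation/scale invariance of the seven combinations
requires. Rotation and scale invariance are exact only in the
continuum; at the blob sizes the tests use (radius 4–8), 90°-rotation
agreement is better than $10^{-6}$ and 2× pixel-replication scaling
agrees within $10^{-2}$ absolute.

## Feature weighting

`relieff()` implements the standard multi-class form with
prior-weighted misses: for each sampled instance, the `k = 8` nearest
same-class neighbors penalize features on which they differ, and the
`k` nearest neighbors of *each* other class, weighted by
$P(C)/(1-P(\mathrm{class}(R)))$, reward them. Distances are Manhattan
on min-max-scaled features, ties broken by sample index; a zero-range
feature contributes `diff = 0`, so constant features score exactly 0.
`m = 20` instances are sampled without replacement (with replacement
only when `m > N`), and `average_weight_runs()` averages 20 full runs
under derived sub-seeds — run-to-run weight variability on the default
synthetic set is small relative to the weight spread, which is what
makes the ranking usable. ReliefF cannot remove *redundant* features;
that is the dimensionality sweep's job (`run_experiment_suite("dims")`),
which adds features in descending weight order and trains the classifier
at each dimension.

## The classifier and its initialization

The classifier is a 6–5–4 sigmoid perceptron by default: the six
retained descriptors ($H_1, H_2, H_3, H_5$, gray variance, entropy),
five hidden neurons, one-hot outputs in fixed class order (rubber,
hair, debris, bubble). The training criterion is the batch error
$\xi = \frac{1}{2S}\sum_n \sum_j (d_{nj} - y_{nj})^2$ and MEA fitness is
$f = 1/\xi$ (a perfect fit maps to the finite sentinel $10^{12}$ so
comparisons stay total). Sum-of-squares with sigmoid outputs, not
softmax/cross-entropy, keeps the loss aligned with the fitness the
evolutionary stage optimizes.

Plain BP is full-batch gradient descent (rate 0.1, at most 5000 epochs,
stop at $\xi \le 10^{-3}$); analytic gradients are verified against
central finite differences in the tests. BP from random weights can
stall in poor local minima and varies across seeds; the MEA stage
replaces the random start with a population search. Its structural
constants are not prescribed anywhere and are this package's own
defaults, chosen from the MEA literature and scaled to desktop
runtimes: 200 individuals in 5 superior plus 5 temporary groups of 20;
similartaxis resamples each group around its best genome with a
Gaussian SD decaying from 0.5 by 0.95 per generation; dissimilation
lets a temporary group that beats the worst superior group displace it,
re-seeding the loser globally; termination after 50 generations or 20
without improvement. The best-so-far fitness is non-decreasing by
construction, and the whole fit is bit-reproducible for a fixed seed.

Feature min-max scaling ranges are learned on training data only,
stored in the model (and its JSON serialization), and applied with
clamping to unseen data.

## What the synthetic scenes emulate — and what they do not

`generate_sequence()` composes, in a fixed and seeded order:
`clamp(background_mean + static texture + per-frame flicker + per-pixel noise)`,
then particles by replacement. Defaults: 64×64 frames, background gray
150, static per-pixel texture offsets uniform in ±8 (embossing, labels),
a single scalar flicker per frame with SD 2 gray levels (light-source
instability is spatially coherent, and observed background variation in
this setting is well under 15 gray levels), independent pixel noise with
SD 2. Opaque particles (rubber ~50, hair ~60, debris ~80) image dark
because they block transmitted light; bubbles image bright (rim ~225,
interior ~170) and are rasterized as disks, so their side ratio is 1.
Rubber is a rigid ellipse; hair a 1–2 px quadratic curve whose bend is
re-perturbed per frame; debris a ragged radial polygon re-perturbed per
frame; trajectories are piecewise-linear waypoints (sinking,
circulating, rising by class) rounded to the nearest pixel. Sequences
default to 50 frames — production lines may capture as few as five
frames per bottle, and the frame count is a config field, but the
background model benefits from a longer warm-up when studying it in
isolation.

`generate_feature_dataset()` draws descriptor vectors directly from
class-conditional Gaussians: classes well separated in gray variance,
entropy and $H_1$–$H_3$, overlapping elsewhere. This is the structure
the weighting stage is expected to uncover, and a nearest-centroid
oracle confirms the default set is >90% separable before any test
relies on it.

What passing tests on these scenes does **not** show: real bottle
footage has refraction, specular reflections, out-of-focus blur,
object fragmentation (one particle splitting into several blobs is the
dominant error source on real lines), and feature distributions far
less Gaussian than the defaults. Detection rates measured here
characterize the algorithms, not an inspection line.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use 64×64×50 sequences for
detection properties, 200-sample sets for weighting, and 300/200
train/test splits with 11 seeds for the BP-versus-MEA-BP comparison —
sizes at which every stage's behavior is already stable and the whole
suite runs in about a minute on one core. All sizes are arguments, and
larger studies only cost time.

## Known limitations

* Single-channel scalar Gaussians only; no color, no shadow model.
* Blobs are classified per frame; there is no cross-frame tracking, so
  the verdict rule (`decision_d` frames with a foreign call fail the
  bottle, default 1) is deliberately conservative.
* The bounding rectangle is axis-aligned, not the rotated minimum
  rectangle; for elongated diagonal shapes f08 understates elongation,
  which the Hu features compensate.
* MEA structural defaults are package choices, not estimates of any
  production system's settings.
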