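# fminspect

Automated visual inspection of liquid pharmaceutical containers:
detection and identification of moving foreign matter (rubber
fragments, hairs, floating debris) versus air bubbles in grayscale
image sequences of a spin-stop transfusion bottle.

When a bottle is spun and stopped abruptly, the liquid vortex keeps
suspended particles moving while the complex container surface
(embossing, labels, scratches) stays static. `fminspect` implements the
full processing chain on 8-bit frame sequences:

1. **Background subtraction** — each pixel is modeled as a mixture of
   K = 3 Gaussians. An observation X matches component i when
   |X − uᵢ| < φσᵢ (φ = 2.5); components rank by wᵢ/σᵢ and the
   background is the smallest rank prefix whose cumulative weight
   exceeds T_R = 0.25. Matched components update with learning rate
   α = 0.05; unmatched observations replace the lowest-weight
   component. Pixels with no match, or matched below the background
   prefix, are foreground.
2. **Blob descriptors** — connected foreground components are labeled
   and described by 15 features: histogram statistics (mean, variance
   σ², smoothness, third moment, uniformity, entropy e), area,
   bounding-rectangle side ratio (exactly 1 for bubbles, which are
   disks), and the seven Hu moment invariants H₁…H₇ computed from
   scale-normalized central moments η_pq = μ_pq / μ₀₀^((p+q)/2+1).
3. **ReliefF weighting** — multi-class instance-based feature quality
   W[A] with k = 8 nearest hits/misses over m = 20 sampled instances,
   averaged across 20 runs; features are then added in descending
   weight order to find the working subspace (default: H₁, H₂, H₃, H₅,
   σ², e).
4. **MEA-BP classification** — a three-layer sigmoid perceptron
   (default 6–5–4) trained on the batch error
   ξ = (1/2S) Σₙ Σⱼ (d_nj − y_nj)², with initial weights and thresholds
   found by the Mind Evolutionary Algorithm (fitness f = 1/ξ;
   similartaxis within groups, dissimilation across groups) and
   fine-tuned by full-batch backpropagation.
5. **Verdict** — a sequence is *qualified* iff no foreign-matter calls
   survive the decision rule (default: any foreign call fails the
   bottle).

A synthetic-scene generator produces frame sequences with exact
ground-truth masks and labeled feature datasets, so the whole pipeline
is testable and reproducible without inspection-line footage. See the
vignette in `vignettes/foreign-matter-detection.Rmd` for the model
details and design choices.

## Worked example

Train a classifier on blobs harvested from simulated scenes, then
inspect a new sequence containing a hair:

```r
library(fminspect)

train <- harvest_labeled_features(n_sequences = 2, n_frames = 20, seed = 4,
                                  frame_height = 48, frame_width = 48)
w <- average_weight_runs(train[feature_names()], train$label, seed = 4)
print(w)
#> ReliefF feature weights (k = 8, m = 20, 20 runs)
#>      f09_hu1      f10_hu2 f08_wl_ratio     f07_area     f01_mean      f11_hu3
#>       0.4404       0.3188       0.2337       0.1891       0.1659       0.1613
#>  f06_entropy      f12_hu4      f14_hu6     f05_unif      f02_var      f13_hu5
#>       0.0526       0.0473       0.0307       0.0262       0.0118       0.0106
#>   f03_smooth       f04_m3      f15_hu7
#>       0.0082       0.0067       0.0027

fit <- mea_bp(train[pipeline_config()$features], train$label, seed = 4)
print(fit)
#> Moving-object classifier (MEA-initialized BP network)
#>   architecture: 6-5-4 (sigmoid)
#>   classes: rubber, hair, debris, bubble
#>   final training error xi = 0.1526, training accuracy = 72.7%

sq <- generate_sequence(scene_config(48, 48, 20,
        particles = list(particle_spec("hair")), seed = 11))
run_detection(sq$frames, fit, sequence_id = "bottle-11")
#> Sequence 'bottle-11': UNQUALIFIED
#>   20 frames (5 warm-up), 25 blob calls
#>
#> rubber   hair debris bubble
#>      0     24     0      1
```

The shape descriptors dominate the weighting (Hu moments and the side
ratio), the harvested-blob training problem is genuinely hard (the
ragged synthetic shapes overlap, hence 72.7% training accuracy on raw
harvested blobs — the parametric feature datasets used for the
classifier experiments separate much more cleanly), and the injected
hair is called in 24 of 25 blob detections, failing the bottle.

A command-line interface wrapping the same functions ships in
`inst/cli/fminspect.R` with subcommands `simulate`, `detect`, `train`,
`select`, `evaluate` and `experiments`.

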