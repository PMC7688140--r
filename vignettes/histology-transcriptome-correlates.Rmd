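---
title: "Correlating convolutional histology features with gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlating convolutional histology features with gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`histotx` links visual phenotypes of stained tissue images to transcriptomes
without a human in the loop. The procedure has five stages:

1. **Tiling.** Whole-slide-style RGB images are cut into non-overlapping
   512x512-pixel tiles on a regular grid anchored at the top-left pixel;
   partial edge windows are discarded. Tiles with less than 50% tissue are
   removed, each kept tile is bilinearly rescaled to 224x224 and normalised
   per channel with the standard ImageNet constants (means 0.485/0.456/0.406,
   s.d. 0.229/0.224/0.225 on the 0-1 scale).
2. **Classification.** A convolutional network is trained to predict the
   tissue label of each tile (momentum SGD on softmax cross-entropy; 90
   epochs, learning rate 0.01 divided by 10 every 30 epochs; the checkpoint
   with the best validation-tile accuracy is kept). Slide-level predictions
   aggregate tile predictions by majority vote. Splits are made at the
   *slide* level (60/20/20, stratified by tissue), never at the tile level,
   so no tile of a held-out slide can leak into training.
3. **Feature quantification.** The network's internal representations are
   turned into location-invariant scalars: for layer `l`, channel `z` and
   input tile `X`, the feature is the spatial aggregate
   `f_lz(X) = sum_{x,y} Y_lzxy(X)^p` of the activation map, with `p = 1` by
   default (the plain sum; equivalent to the spatial average up to the
   constant map area). Slide-level features sum over the slide's tiles,
   which makes `f_lz(W)` exactly additive over any partition of the tiles.
4. **Correlation screening.** Gene expression is transformed to
   `log2(1 + E)`; duplicate expression samples of a slide are averaged on
   that scale. Genes whose maximal per-tissue median is below a threshold
   `E_T` are excluded. For the remaining genes, every (gene, feature) pair
   gets a Pearson correlation over the *test-split* slides only; pairs with
   `|r| >= R_T` are selected and summarised (pairs, unique genes, unique
   features, unique tissues via each gene's tissue of maximal expression).
   Significance is assessed by permutation (add-one estimator, so the
   smallest attainable p at N = 1000 permutations is 1/1001), and
   reproducibility across sample sets by correlating Fisher-z-transformed
   correlation vectors.
5. **Conditional-independence analysis and visualization.** Because the
   classifier is trained on tissue labels and many genes are
   tissue-specific, a gene-feature correlation can be indirect via tissue
   identity. The partial correlation `r(g, f | t)` is computed by centring
   both vectors within tissue groups (identical to residualising on the
   tissue one-hot design) and tested with
   `t = r * sqrt((n - 2 - k) / (1 - r^2))`, `k = #tissues - 1`. A pair is
   flagged `g-t-f` indirect when this test fails to reject at `alpha`. The
   two patterns that condition on a scalar and test the categorical tissue
   (`f-g-t`, `g-f-t`) use a joint F-test on the tissue indicator block after
   removing the scalar covariate. Features are visualised by guided
   backpropagation (gradients zeroed at each ReLU where the forward input
   was non-positive or the incoming gradient negative) and by activation
   maximization (regularised gradient ascent from random noise).

# The architecture catalog

`build_architecture()` covers the standard families (AlexNet, VGG 11-19 with
and without batch normalisation, ResNet34, Inception v3) plus two bespoke
single-head VGG16 variants (`vgg16_1fc`: dropout + one linear layer on the
25088-dimensional conv output; `vgg16_avg1fc`: global 7x7 average pool,
dropout, one 512-to-C linear layer) and the desk-scale `tiny` network.
Feature enumeration follows per-family conventions:

* AlexNet/VGG: every conv, batchnorm, ReLU and pooling layer of the feature
  part contributes one feature per channel. Dropout appears only in heads
  and has no activation channels. Batchnorm layers *are* counted in the
  `_bn` variants.
* ResNet34: layers inside a residual block do not form complete
  representations (their outputs are added to a skip connection), so only
  the stem ReLU/maxpool and each block's post-addition ReLU are eligible.
* Inception v3: only elementary layers with non-negative outputs (ReLU,
  max/avg pooling) off the auxiliary branch; concatenated block outputs
  re-list their inputs and are excluded as redundant.

Parameter counts are closed-form sums over the declared weight/bias tensors
and are exact; they are the package's acceptance anchors because they are
architecture-determined, independent of data and training.

The `tiny` network (the only one the package trains) is fixed: a stem 2x
average pool (halving the 224x224 input so CPU convolutions stay fast),
three conv(3x3)/ReLU/maxpool blocks with 8/16/32 channels and pool sizes
4/2/2, and a linear head on the 7x7x32 map — 171 features, 12,308 trainable
parameters at 4 classes. The engine underneath is a plain dense
implementation (im2col convolutions via BLAS, manual reverse mode) with
finite-difference-checked gradients; it exists because the package needs
full control over activation capture, guided ReLU masking and input
gradients at desk scale.

# The synthetic data generator

The generator emulates the statistical structure the analysis assumes, not
histological appearance. Slides are disk textures: coloured "cells" on a
white background. Three per-slide latents each combine a class base with
within-class variation:

* `cell_radius` (px): class bases 8/10/12/14, within-class s.d. 1.0;
* `cell_density` (cells per 1e4 px^2): bases chosen as
  `16000 / (pi * radius^2)` so expected disk coverage is ~80% in every
  class, keeping tiles comfortably above the 50% tissue filter;
* `palette_hue` (0-1 hue circle): class bases evenly spaced, within-class
  s.d. 0.05 — wide enough that colour-sensitive channel sums can recover
  the latent at desk-scale sample sizes, narrow enough to stay visually
  within the class palette.

Genes come in three planted types: **direct** genes track one latent with a
stated theoretical correlation (default rho = 0.9, slope signs alternating),
**tissue markers** are shifted up by 4 log2 units in one class and are
independent of the latents given the class (the `g-t-f` indirect
configuration), and **null** genes are pure noise. Log-scale expression is
inverted to a raw scale as `E = 2^x - 1` (x clamped at 0), so the pipeline's
`log2(1 + E)` transform is an exact round trip. 10% of slides receive a
duplicate expression sample with fresh noise, exercising the duplicate
resolution step.

The default recipe is 4 classes x 30 slides, 1024x1024 images (four tiles
each) and 60 genes (20/20/20). What the generator does *not* emulate:
staining variation, scanner artifacts, nuclear morphology, or spatial
substructure within a tissue. Passing the recovery tests therefore shows
that the pipeline's statistics behave as designed on data with known truth —
not that the method is validated on real histology.

# Numerical and design choices

* **Tissue detection**: a pixel is background when `min(R, G, B) >= 220`
  (near-white); the tissue fraction is the complement. This is the simplest
  reproducible criterion; the threshold is exposed.
* **Resize filter**: separable bilinear interpolation with pixel-centre
  alignment, implemented in-package so the convention is exactly specified
  and testable against closed forms.
* **Expression filter direction**: genes are *kept* when their maximal
  per-tissue median log2 expression is at least `E_T` — low-expression genes
  are what the filter removes.
* **Selection statistic**: `|r| >= R_T` by default; a signed mode is
  available (`use_abs = FALSE`).
* **Duplicate samples**: averaged on the log scale (variance-reducing,
  deterministic).
* **Optimizer details** beyond the learning-rate schedule: momentum 0.9,
  weight decay 1e-4, He-style initialisation, no augmentation. Validation
  ties across epochs resolve to the earliest epoch; majority-vote ties to
  the larger summed softmax score, then the lowest class index.
* **Permutation p-values** use the add-one estimator
  `(1 + #{|r_perm| >= |r_obs|}) / (N + 1)`; constant inputs are flagged
  degenerate with p = 1. Benjamini-Hochberg q-values are reported as a
  clearly supplementary column — the screening itself uses the fixed
  thresholds plus permutation, nothing more.
* **Representative tiles** for guided backpropagation are the top-k by
  tile-level feature value with a per-slide cap (deterministic ties by tile
  identity) — a simple documented selection rule.
* **Activation maximization** defaults: 256 steps of size 0.05 in
  normalised input space, +/-2 px random circular jitter per step, Gaussian
  blur (sigma 0.5) every 4 steps, L2 weight 1e-4, clamping to the
  normalised range of valid 8-bit inputs. The ascent contract (final value
  above initial) holds with regularisers on; strict per-step monotonicity
  is a property of the unregularised ascent.
* **Conditional-independence flag rule**: a pair is flagged indirect when
  the CI test *fails to reject* (`p >= alpha`). Note the degenerate limits:
  at very small `alpha` more pairs are flagged, not fewer.

# Problem sizes used by the test suite

The suite verifies every stage at sizes a single CPU handles in minutes: the
architecture table is exact and instantaneous; permutation calibration uses
1000 null pairs at 200 permutations; partial-correlation pattern recovery
uses n = 300 samples over 100 seeds; the end-to-end run uses the default
synthetic recipe with the tiny classifier trained for 15 epochs. The
end-to-end checks assert tile accuracy of at least 0.9, recovery of at least
80% of direct genes at `|r| >= 0.6` on the test split, and no such feature
for at least 90% of null genes.

# Limitations

* Training is desk-scale by construction; the large catalog architectures
  are counted exactly but not trained. The engine is single-threaded,
  dense, CPU-bound.
* The ResNet34/Inception feature-eligibility rules are conventions over
  printed architecture structure; they determine which channels are
  enumerated, nothing about trained behaviour.
* Correlation screening is univariate by design (samples are few relative
  to genes x features); it finds candidates, not causes. Partial
  correlations at small test-split sizes have limited power to separate
  direct from tissue-mediated pairs — the CI analysis is informative at
  larger sample sizes.
* The synthetic generator's realism limits are listed above; conclusions
  about real histology require real paired data.
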