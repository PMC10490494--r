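---
title: "Methods: autoencoder clustering and improved U-Net for nuclei segmentation"
author: "nucseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autoencoder clustering and improved U-Net for nuclei segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hematoxylin-and-eosin (H&E) staining renders cell nuclei dark
bluish-purple and cytoplasm/stroma pink. Nucleus segmentation — deciding
for every pixel of a histopathology tile whether it belongs to a nucleus
— underpins morphometric analysis in breast-cancer pathology, but
pixel-accurate annotations are expensive, which motivates methods that
can work without them. `nucseg` implements two complementary pipelines
over the same patching, evaluation and I/O infrastructure:

* **Unsupervised branch.** A convolutional autoencoder (CAE) is trained
  to reconstruct image patches; its bottleneck codes are clustered with
  2-means; the two clusters are mapped onto {nucleus, background}; each
  pixel inherits the class of the patch(es) covering it.
* **Supervised branch.** A patch-based "improved" U-Net — encoder/decoder
  with skip connections and extra convolutions per block — trained with a
  pixel-wise softmax cross-entropy against ground-truth masks, plus an
  AlexNet-style fully convolutional network (FCN) baseline trained under
  the identical protocol.

## The unsupervised model

The autoencoder is parameterized by the triple `(N, C, Z)` plus the
square input edge (a `NetworkSpec`): `N` encoder levels, each
`[3x3 convolution -> batch normalization -> ReLU -> 2x2 max pooling]`
with filters doubling from `C`; a dense information bottleneck of `Z`
units; a mirrored decoder (2x2 transposed convolution, 3x3 convolution,
batch norm, ReLU per level) ending in a sigmoid so reconstructions lie in
`[0, 1]`. Training minimizes the per-pixel mean squared reconstruction
error with Adam.

Defaults are `N = 3`, `C = 16`, `Z = 64`, input `32`: the bottleneck
(64 values) is a 48-fold compression of the 32x32x3 input, and
`32 / 2^3 = 4` keeps the pooled extent integral. "A normalization" is
realized as batch normalization — the standard choice for this
architecture family — with running statistics (momentum 0.9) used at
inference so that encoding is deterministic for fixed weights.

2-means clustering runs Lloyd iterations (via `stats::kmeans`) from
k-means++ initializations, takes the best of `nRestarts = 10` by
within-cluster sum of squares, and assigns points to the nearest
centroid with ties broken toward the lower centroid index. On inputs of
up to 24 points every distinct pair of points is additionally used as a
deterministic seeding: restart-limited Lloyd alone can stall in a local
optimum even at that scale, and the extra seedings let tiny instances
reliably reach the optimum that the tests verify by exhaustive
enumeration. A set of
all-identical codes raises a degenerate-input error rather than
returning an empty cluster. On every instance small enough to enumerate,
the fitted inertia is checked in the tests against the exhaustive
optimal bipartition.

Clustering leaves the clusters anonymous; the **cluster-to-class
correspondence** is resolved in one of two ways:

* with reference masks (evaluation mode), the bijection maximizing pixel
  accuracy is chosen; exact ties fall back to "cluster 1 = background";
* without references (deployment mode), the cluster whose member patches
  have the lower mean Rec.-601 luminance is called nucleus — the
  hematoxylin-dark heuristic. An empty cluster counts as light
  background.

Patch-level granularity is inherent to this branch: every pixel of a
patch receives the patch's class. Whether codes should be computed per
patch or per whole image is genuinely open in this design; we cluster
per patch because only sub-image codes can produce sub-image
segmentation. With the default non-overlapping stride the output is
blocky at the patch scale; `segmentUnsupervised()` therefore accepts an
overlapping stride, in which case every pixel takes the majority vote
over all covering patches (ties to foreground, favoring nuclei recall).

## The supervised model

`SegNetworkSpec` describes both supervised networks. The U-Net encoder
has `depth` blocks of `convsPerBlock` x `[3x3 conv -> BN -> ReLU]`
followed by 2x2 max pooling, a bottom block, and a symmetric decoder of
2x2 transposed convolutions ("up-convolutions") each concatenated with
the matching encoder feature map; the head is a 1x1 convolution to
`nClasses` followed by the pixel-wise softmax

p_k(x) = exp(a_k(x)) / sum_k' exp(a_k'(x)),

numerically stabilized by subtracting the per-pixel maximum (the
expression is invariant to per-pixel constant shifts, which the tests
exercise directly). `convsPerBlock = 2` recovers the classic U-Net
block; the *improved* variant defaults to 3, adding one convolution per
encoder/decoder block. The published description of the improvement —
"new layers in the encoder and decoder parts" — does not pin down an
exact count or placement, so the knob covers any reasonable reading and
the parameter-count ordering (improved > classic) is asserted in tests.

The FCN baseline follows the classic fully-convolutional recipe on an
AlexNet-style encoder: a large 7x7 first kernel, 5x5 second, 3x3
afterwards, no skip connections; the former fully connected layers are
recast as convolutions; a 1x1 classifier produces coarse class scores
that `depth` transposed convolutions upsample back to full resolution.
Following the classic FCN recipe, the transposed convolutions are
initialized to exact interpolation of the class scores (the
nearest-neighbor equivalent for 2x2 stride-2 kernels) rather than to
random weights, so the coarse classifier is usable from the first epoch;
the layers remain fully trainable.
It is trained from scratch with exactly the same loss, optimizer,
budget, data and seeds as the U-Net, which makes the IoU ordering
between the two architectures a meaningful comparison. (Whether the
original baseline reused pretrained classification weights is ambiguous;
training from scratch is the reproducible choice.)

Training minimizes pixel-wise softmax cross-entropy with Adam
(`learningRate = 1e-3`, unstated in the source material and fully
configurable). Prediction tiles an image with reflect padding, averages
class probabilities over covering tiles, and takes the per-pixel argmax
with probability-0.5 ties resolved to foreground.

## Patching, padding and augmentation

Images are divided into square patches (default 32, matching the
published preprocessing) on a regular grid, left-to-right then
top-to-bottom, with 0-based row/column coordinates. When the extent is
not an exact multiple, the bottom/right are reflect-padded (mirror
without repeating the edge sample) to the smallest covered size; the
published 512/32 case divides evenly so the rule is this package's
choice, made to avoid border artifacts, and `assembleMask()` crops the
padding away so extract-then-assemble is exactly the identity.

A mask patch is labeled tumor when its foreground fraction reaches
`positiveFraction` (default 0.5, a symmetric majority rule — the ground
truth-based patch classification is published without a threshold).

Augmentation is rotation only, matching the method actually used.
Right-angle rotations are exact pixel permutations; arbitrary angles use
inverse-mapped bilinear resampling for images and nearest-neighbor for
masks (so masks stay binary) with reflect fill on the original canvas.

## Evaluation

Pixel confusion counts (foreground = positive) feed the five standard
metrics: precision TP/(TP+FP), recall TP/(TP+FN), F1 = 2RP/(R+P),
accuracy (TP+TN)/total and IoU TP/(TP+FP+FN). Two policies matter:

* a metric whose denominator is zero is reported as `NA` ("undefined"),
  never silently 0 or 1, and is excluded from aggregate means;
* evaluation always happens on the original, unpadded extent.

`per_image` reporting (one row per image plus an unweighted mean of
defined values) is the default; `pooled` mode sums counts first. The
algebraic identity F1 = 2·IoU/(1+IoU) links the two overlap metrics and
is verified to 1e-12 wherever both are defined.

## The synthetic generator as study conditions

Real H&E data cannot ship with the package, so every pipeline is
exercised on synthetic tiles: filled ellipses (random center,
orientation, semi-major axis, eccentricity) in a hematoxylin-like color
(0.35, 0.25, 0.55) on an eosin-like background (0.90, 0.75, 0.80), with
per-channel additive Gaussian noise clipped to `[0, 1]` applied to the
image only — the mask marks the rendered foreground exactly, before
noise. Overlapping ellipses union into one mask, mirroring the
overlapping-nuclei regime the methods target. All draws derive from one
seed, so generation is bit-reproducible.

What the generator emulates: the luminance and hue contrast between
nuclei and stroma, elliptical and overlapping nuclei, pixel-exact
annotation, moderate sensor noise. What it does not: stain variability
between slides, texture inside nuclei and stroma, out-of-focus regions,
touching-nucleus boundaries with shared gradients, and annotation noise.
Passing the end-to-end recovery tests therefore shows the pipelines are
implemented coherently and can recover structure under the stated
contrast and noise, not that they reach any particular accuracy on real
histology; published full-scale results on real data (200-epoch GPU
training) are out of desk-scale reach and are deliberately not numeric
targets here.

## Benchmark problem sizes

The reproducible benchmarks (`benchmarkCAE()`, `benchmarkUnsupervised()`,
`benchmarkSupervised()`) fix the package's reference experiments, chosen
so a laptop-class single core completes each in minutes:

* *Autoencoder learning*: 200 synthetic 32x32 patches, default
  `(N=3, C=16, Z=64)` network, 20 epochs; the final/initial loss ratio
  is the reported quantity.
* *Unsupervised recovery*: 20 images of 128x128 with 8 nuclei each and
  noise 0.02 (the "easy", high-contrast set); an 8x8-input autoencoder
  (depth 2, 8 filters, 16 latent units) trained 8 epochs on
  non-overlapping patches; segmentation with stride 4 and majority
  voting. The small patch and overlapping stride are what make
  pixel-level IoU meaningful under patch-granular labels.
* *Supervised recovery*: 64 training and 16 held-out 64x64 tiles with
  3 nuclei each; improved U-Net (depth 3, 8 base filters, 3 convs per
  block) and the FCN baseline trained 30 epochs, batch 8, shared seeds;
  held-out mean IoU for both and their ordering are the reported
  quantities.

## Numerical choices and degenerate inputs

* Weights: He-normal initialization, seeded, so builds are reproducible.
* Batch norm: biased batch variance, eps 1e-5, running-stat momentum
  0.9; inference uses running statistics.
* Adam: beta1 0.9, beta2 0.999, eps 1e-8.
* Softmax and cross-entropy are max-stabilized; log arguments are
  floored at 1e-12.
* Max-pool argmax ties take the earliest (top-left) position; k-means
  assignment ties take the lower centroid index; patch-vote and
  probability ties take foreground; mapping-accuracy ties take
  "cluster 1 = background". Every tie rule is deterministic and
  documented where it surfaces.
* Empty patch lists, empty datasets, non-binary masks, shape mismatches,
  unmapped cluster models and untrained predictors raise immediate,
  named errors rather than propagating silently.

## Reproducibility

Every stochastic entry point takes a seed and restores the caller's RNG
state; identical inputs and seeds reproduce histories, codes and masks
bit-identically on the same BLAS. The network engine itself is
deterministic (no dropout, no stochastic layers), so within one machine
the only seed-dependent choices are initialization, shuffling and the
synthetic data.

## Known limitations

* The network engine is a compact CPU implementation sized for
  patch-scale inputs; it is not a general deep-learning framework and
  has no GPU path.
* Patch-level cluster labels bound the unsupervised branch's spatial
  precision by the stride; stride-1 voting approaches pixel granularity
  at quadratic cost.
* The luminance heuristic for cluster-to-class mapping assumes
  hematoxylin-dark nuclei on a lighter background; inverted stains would
  need the reference-mask mode.
* Whole-slide (pyramidal) formats are out of scope; the package operates
  on fixed tiles.
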