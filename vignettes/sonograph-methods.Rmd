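---
title: "Graph-based classification of breast ultrasound lesions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based classification of breast ultrasound lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Radiologists separate benign from malignant breast lesions on ultrasound
by a small set of visual markers: benign masses tend to be round or
oval, smooth-bordered, internally homogeneous and sharply rimmed, while
malignant masses are irregular, spiculated, heterogeneous and diffusely
bordered. SonoGraph encodes those markers as ten quantitative features
of a segmented lesion, relates images to each other through the rank
correlation of their feature profiles, and classifies every image
jointly as a node of one graph rather than in isolation.

The pipeline is: extract the lesion region of interest (ROI) by masking
the image with its ground-truth segmentation; compute the ten features
per image into an *n* x 12 node table (id, ten features, class);
compute the Spearman correlation of every pair of feature rows to get
*n(n-1)/2* weighted edges; optionally remove class-anomalous edges and
threshold on the correlation score; then train a graph neural network
(GNN) transductively on the resulting graph and evaluate on held-out
nodes.

## The ten features

Shape and boundary features operate on the binary mask:

* **Circularity** `4 a_T / (pi d_max^2)` with `a_T` the pixel count and
  `d_max` the major-axis length of the moments-equivalent ellipse
  (4 times the square root of the largest eigenvalue of the coordinate
  covariance, with a 1/12 pixel-extent correction so single-pixel and
  thin regions stay finite). 1 for a disk.
* **Solidity** — area over convex-hull area. The hull area is counted
  in pixels (centers inside or on the hull polygon), which keeps the
  ratio in (0, 1] under discretization.
* **Ellipse ratio** — area of the minimum-area ellipse enclosing the
  boundary pixels divided by the lesion area. The ellipse is fitted
  with the Frank–Wolfe/away-step algorithm for the dual D-optimal
  design problem on the hull vertices of the boundary (tolerance 1e-6
  on the optimality gap; the away steps give linear convergence where
  the plain update stalls sublinearly).
* **Brightness** — rim sharpness: with a distance map of the mask, the
  absolute difference between the mean intensity of the surrounding
  tissue within *k* pixels outside the boundary and the outer lesion
  band within *k* pixels inside it. *k* defaults to 10 px and is a
  configuration key, as no canonical value exists.

Texture features operate on mask-foreground pixels only. The ROI
extraction zeroes the background, and if histograms or co-occurrence
counts included those zeros they would dominate every statistic, so
both pixels of every counted pair must lie inside the mask:

* **Shannon entropy** and **histogram energy** of the 8-bit intensity
  histogram (log base 2; `0 log 0 := 0`; energy is the sum of squared
  proportions).
* **GLCM entropy, correlation, dissimilarity, contrast** from one
  gray-level co-occurrence matrix accumulated over the four standard
  directions (0, 45, 90, 135 degrees) at distance D, symmetrized and
  normalized to sum 1. Quantization defaults to G = 8 uniform bins of
  [0, 255] and D = 1; both are configuration keys with declared, not
  derived, defaults. Correlation is
  reported in the variance-normalized form (divide by the gray-level
  variance) so it lies in [-1, 1]; the unnormalized second-moment sum
  is available behind `normalizedCorrelation = FALSE`. A degenerate
  one-level matrix reports correlation 1.

## Feature significance

`featureTTest()` runs a two-sample test per feature, benign minus
malignant. We use Welch's unequal-variance form written out directly
rather than `stats::t.test`: class sizes and variances differ in
practice, and the explicit formula also covers zero-variance groups
(identical constants give t = 0, p = 1; separated constants give an
infinite statistic and p = 0) where the library refuses. No
multiple-testing correction is applied by default, matching
per-feature reporting; Bonferroni is available. Density curves per
class use a plain Gaussian kernel on an explicit grid with Silverman's
rule as default bandwidth.

## Graph construction

The Spearman score of two feature rows is the Pearson correlation of
their average ranks; with no ties this equals the classical
`1 - 6 sum(d^2) / (n (n^2 - 1))`. Average ranks are used because
quantized features can tie, and the classical formula is biased under
ties. A constant row has no defined correlation and is an error, not a
silent NaN. Node ids are 1-based (the natural indexing in R; exported
CSVs use the same convention). Edges are undirected, stored once with
`source < target`, and negative weights are kept in the unthresholded
graph since only lower-bound thresholds are ever applied.

Thresholding keeps edges with weight >= tau; the special row "exactly
1.0" is implemented as equality within 1e-12, since rank correlations
of identical rank profiles are exactly 1 up to floating-point noise.
Adjacency is dense below 2000 nodes and sparse above, with identical
semantics.

**Anomaly filtering.** Edges are banded at two fixed cut points
(defaults 0.4 exclusive, 0.7 inclusive): strong edges joining distinct
classes and weak edges joining the same class are removed; the middle
band always passes through. The two predicates act on disjoint weight
ranges, so the filter is idempotent, order-independent, and exactly
count-conserving — the emitted `FilterReport` makes the arithmetic
auditable (`final = total - strongCrossRemoved - weakSameRemoved`).

## The classifier

Node features pass through a stack of feed-forward (FFN) blocks, then
three graph-convolution layers, a skip combination, further FFN blocks,
and a 2-way softmax head. Each FFN block is batch normalization,
dropout (rate 0.2), and two 64-unit dense layers with ELU, wrapped in
an additive skip connection (a linear projection where widths change).
With nine blocks total we place ceiling(9/2) = 5 before the
graph-convolution stack and 4 after — the split is a declared design
choice.

One message-passing layer computes
`h'_u = sigma(W_n h_u + W_nei agg_{v in N(u)} h_v + b)` followed by
row-wise L2 normalization of the embeddings. The neighbor aggregate
defaults to the degree-normalized mean (raw sum available): embeddings
are stated to be normalized without a formula, and mean aggregation
plus L2 normalization keeps embedding scales independent of degree,
which varies by orders of magnitude across thresholds.

The skip path from the pre-GCN representation is combined with the
GCN output either by concatenation plus a dense layer, or (default) by
a two-step convolutional-recurrent cell that consumes the sequence
[skip, transformed] and emits its final state. The single-gate
formulation keeps both combination options runnable and directly
comparable in ablations.

Training is transductive: message passing always sees the full
adjacency, while the sparse categorical cross-entropy loss is computed
on mini-batches (size 128) of training nodes only. Batch-norm uses
batch statistics over the full node set in training and running
averages at inference — standard semantics, declared here because the
alternative (statistics over loss batches) is equally defensible. The
default optimizer is Nadam at learning rate 0.01 for 100 fixed epochs
(no early stopping). The split is stratified 80/10/10 by class,
seeded; the proportions are a declared default. All randomness —
initialization, dropout, batching, folds, tuner — flows through one
seeded generator; identical seeds give bit-identical runs. Forward and
backward passes are written out explicitly (there is no autograd
framework in this stack), and the backward pass is verified against
central finite differences in the test suite.

Evaluation reports the full confusion-matrix suite (accuracy,
sensitivity/recall, specificity, precision, NPV, FPR, FDR, FNR, F1,
MCC) in percent; metrics with zero denominators are NaN with a flag,
never silent zeros. Cross-validation is stratified k-fold (default 5)
with the arithmetic mean of fold accuracies.

**Hyperparameter tuning** maximizes a black-box objective (typically
validation accuracy) over the box {hidden units 32–64, learning rate
0.001–0.01, batch size 64–128, dropout 0.3–0.7} with a Gaussian-process
surrogate (RBF kernel, length-scale 0.3 in the unit cube, standardized
response) and the upper-confidence-bound rule mean + kappa sd,
kappa = 2. The initial design is a Latin hypercube; integer dimensions
are rounded after acquisition, so every proposal satisfies the bounds.

## The HOG baseline

The comparison arm replaces the ten ROI features with a dense
histogram-of-oriented-gradients descriptor of the whole image, no mask
involved: 224 x 224 input, 16 x 16-pixel cells, 2 x 2-cell blocks at
one-cell stride, 9 unsigned orientation bins — the geometry that yields
a 6084-long vector (13 x 13 blocks x 4 cells x 9 bins). We use
unsigned gradients on [0, 180) and L2-Hys block normalization
(epsilon 1e-5, clip 0.2), the standard choices. The descriptor rows
then follow the identical Spearman-graph + GNN path.

## The phantom generator

`generatePhantom()` emulates the statistical contrasts the ten features
measure, not ultrasound physics. A lesion is a star-convex region
`r(theta) = r0 (1 + irregularity * sum of sine harmonics + spicule
spikes)` — this contour family gives direct, continuous control over
circularity, solidity and the ellipse ratio. The interior carries a
band-limited sinusoidal heterogeneity field (controls the entropies and
GLCM statistics), the background sits `rimContrast` gray levels away
from the lesion mean (controls brightness), and multiplicative
Rayleigh-like speckle over the whole image mimics the modality's
dominant noise source before clipping to 8 bits. Masks are cleaned to
one 4-connected component strictly inside the border.

Class presets (stored as data in `phantomPresets()`, overridable per
cohort) were fixed once at values a reader of the clinical literature
would call typical: benign — near-elliptical (irregularity 0.03, no
spicules), homogeneous (heterogeneity 0.08), light speckle (0.06),
bright sharp rim (+60 gray levels); malignant — irregular (0.25), seven
spicules, heterogeneous (0.45), heavy speckle (0.18), weak rim (+25).
The default study cohort is 50 benign + 50 malignant 256-px phantoms.

What the phantoms do **not** model: beamforming, attenuation, acoustic
shadowing, posterior enhancement, anatomical context, or segmentation
error (masks are exact by construction). Tests passing on phantoms
demonstrate that the feature definitions respond to the intended
geometric and textural contrasts and that the full pipeline recovers a
separable cohort; they say nothing about accuracy on clinical images.

## Numerical choices and degenerate inputs

* Masks binarize at > 0; coordinates are (row, column) pixel centers.
* Empty masks, all-zero masks after ROI extraction, collinear regions,
  constant feature rows, missing node labels and empty train/val/test
  splits are all hard errors with named messages, not warnings.
* The enclosing-ellipse fit runs to a 1e-6 optimality-gap tolerance
  with a 100,000-iteration cap; softmax subtracts the row maximum;
  dropout uses inverted scaling; batch-norm epsilon is 1e-5; probability
  floors at 1e-12 guard the loss.
* Ties in ranks use average ranks throughout.

## Problem sizes in the shipped tests

The test suite exercises phantoms at 96–128 px (30 + 30 shared
cohort), monotonicity protocols at three amplitude levels with n = 30
per level, oracle comparisons for the Spearman score at 1000 random
pairs, the GLCM against pair enumeration on ROIs up to 32 x 32, a
1000-replicate null calibration of the t-test, and one full 50 + 50
cohort at the 256-px default for the end-to-end and five-fold checks.
These sizes were chosen as the smallest that make the statistical
assertions stable.

## Known limitations

* The GNN is plain R matrix algebra: fine for hundreds of nodes,
  not for tens of thousands.
* The anomaly filter consumes node labels, so on real data it can only
  be applied to the labeled portion of a graph.
* Only binary benign/malignant classification is supported; a "normal"
  (no lesion) class is out of scope.
* The phantom generator's fidelity limits are listed above.
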