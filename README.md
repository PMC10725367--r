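# SonoGraph

Graph neural network classification of breast ultrasound lesions from
clinically significant image features.

## What it does

Radiologists grade breast masses on ultrasound by shape, margin and
internal texture: benign lesions are typically round, smooth, sharply
rimmed and homogeneous; malignant ones irregular, spiculated, diffusely
rimmed and heterogeneous. SonoGraph turns those markers into a
graph-based classifier:

1. **Features.** From each lesion ROI (image masked by its segmentation)
   it computes ten features: circularity `4·a_T/(π·d_max²)`, solidity
   (area / convex hull), enclosing-ellipse ratio, boundary brightness
   (distance-map band contrast), Shannon entropy, histogram energy
   `E = Σ r(i)²`, and GLCM entropy, correlation, dissimilarity
   `Σ r_ij |i−j|` and contrast `Σ r_ij (i−j)²`.
2. **Graph.** Rows of the n × 12 node table (id, ten features, label)
   become nodes; every pair of images gets an edge weighted by the
   Spearman rank correlation `S = 1 − 6 Σ d² / (n(n²−1))` of their
   feature rows (average ranks under ties). Edges can be thresholded
   (keep `S ≥ τ`) and cleaned of class anomalies — strong (`S ≥ 0.7`)
   edges between classes and weak (`S < 0.4`) edges within a class.
3. **Classifier.** A transductive GNN: skip-connected feed-forward
   blocks (batch norm, dropout 0.2, two 64-unit ELU dense layers)
   around three graph-convolution layers
   `h'_u = σ(W_n h_u + W_nei Σ_{v∈N(u)} h_v + b)`, softmax output,
   trained with Nadam (lr 0.01, batch 128, 100 epochs, sparse
   categorical cross-entropy). Includes stratified k-fold CV, a
   threshold sweep, Gaussian-process Bayesian hyperparameter tuning
   (UCB acquisition), and a HOG-descriptor baseline arm (224 × 224,
   16-px cells, 2 × 2-cell blocks, 9 bins → 6084-long descriptors) run
   through the identical graph pipeline.

A seeded phantom generator produces benign-like and malignant-like
lesion image/mask/label triplets with controllable boundary
irregularity, spiculation, texture heterogeneity, speckle and rim
contrast, so the entire pipeline is testable without any clinical data.

## Worked example

```r
library(SonoGraph)

cohort <- generateCohort(25, 25, seed = 42, imageSize = 128)
ft <- buildFeatureTable(cohort)
ft
#> FeatureTable: 50 images x 10 features (benign=25, malignant=25)

g <- buildGraph(ft, tau = 0.95)
g
#> LesionGraph: 50 nodes, 10 features, 603 edges

fit <- trainGNN(g, gnnConfig(epochs = 60L, seed = 1L))
fit$report
#> EvalReport: TP=2 FP=0 TN=2 FN=0
#>   accuracy: 100.00
#>   sensitivity: 100.00
#>   ...
#>   mcc: 100.00
```

Only 603 of the 1225 possible edges survive the 0.95 threshold, and
almost all of them join same-class nodes — the feature profiles of the
two phantom classes rank-correlate within class far more than across.
The report is the confusion matrix of the held-out test nodes (a
stratified 80/10/10 split) plus the full metric suite in percent.
`featureTTest(ft)` gives the per-feature Welch t-statistics,
`plotFeatureDensities(ft, "densities.png")` the per-class density
panels, `kfoldCV(g)` the five-fold accuracies, and `runPipeline()`
chains everything and writes every intermediate table plus a run
manifest. A thin command-line wrapper with per-stage subcommands is in
`inst/scripts/sonograph.R`.

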