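Package: SonoGraph
Title: Graph Neural Network Classification of Breast Ultrasound Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies breast ultrasound lesions as benign or malignant
    with a graph neural network built on clinically significant features.
    Ten morphological, intensity and texture features (circularity,
    solidity, enclosing-ellipse ratio, boundary brightness, Shannon
    entropy, GLCM entropy/correlation/dissimilarity/contrast, histogram
    energy) are extracted from lesion regions of interest; an
    image-to-image graph is built from Spearman rank correlations of the
    feature rows, optionally thresholded and cleaned of class-anomalous
    edges; nodes are classified transductively with skip-connected
    feed-forward blocks around graph-convolution layers. Includes a seeded
    phantom generator emulating benign and malignant lesion appearance, a
    HOG-descriptor baseline arm, feature significance testing, k-fold
    cross-validation, and Gaussian-process Bayesian hyperparameter tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, graphics, Matrix, png,
    EBImage, igraph, jsonlite, yaml, withr, lhs, pracma
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
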