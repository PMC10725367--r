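#' @import methods
NULL

#' Names of the ten lesion features
#'
#' Column order used throughout: morphological features first
#' (circularity, solidity), then texture (entropies, GLCM statistics,
#' histogram energy), then the enclosing-ellipse ratio and boundary
#' brightness.
#'
#' @return Character vector of length 10.
#' @export
featureNames <- function() {
  c("circularity", "solidity", "shannon_entropy", "glcm_entropy",
    "glcm_correlation", "glcm_dissimilarity", "glcm_contrast",
    "hist_energy", "ellipse_ratio", "brightness")
}

#' PhantomSpec: parameters of one synthetic lesion phantom
#'
#' Describes a star-convex lesion drawn into a speckled background.
#' `boundaryIrregularity` is the amplitude of smooth radial harmonics of
#' the contour; `nSpicules` adds sharp radial spikes; `textureHeterogeneity`
#' scales a band-limited intra-lesion intensity field;
#' `speckleSigma` is the relative standard deviation of the multiplicative
#' Rayleigh speckle; `rimContrast` is the background-minus-lesion mean
#' intensity difference in 8-bit units.
#'
#' @slot imageSize integer, square image side in pixels (>= 64)
#' @slot classLabel "benign" or "malignant"
#' @slot boundaryIrregularity numeric >= 0
#' @slot nSpicules integer >= 0
#' @slot textureHeterogeneity numeric >= 0
#' @slot speckleSigma numeric >= 0
#' @slot rimContrast numeric (intensity units)
#' @slot seed integer RNG seed; identical specs give bit-identical output
#' @export
setClass("PhantomSpec", representation(
  imageSize = "integer",
  classLabel = "character",
  boundaryIrregularity = "numeric",
  nSpicules = "integer",
  textureHeterogeneity = "numeric",
  speckleSigma = "numeric",
  rimContrast = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  if (length(object@imageSize) != 1L || is.na(object@imageSize) ||
      object@imageSize < 64L)
    msg <- c(msg, "invalid spec: imageSize must be a single integer >= 64")
  if (!object@classLabel %in% c("benign", "malignant"))
    msg <- c(msg, "invalid spec: classLabel must be 'benign' or 'malignant'")
  amps <- c(object@boundaryIrregularity, object@textureHeterogeneity,
            object@speckleSigma)
  if (any(!is.finite(amps)) || any(amps < 0))
    msg <- c(msg, "invalid spec: amplitudes must be finite and >= 0")
  if (is.na(object@nSpicules) || object@nSpicules < 0L)
    msg <- c(msg, "invalid spec: nSpicules must be >= 0")
  if (!is.finite(object@rimContrast))
    msg <- c(msg, "invalid spec: rimContrast must be finite")
  if (is.null(msg)) TRUE else msg
})

#' FeatureTable: one row of lesion features per image
#'
#' Rows are images (graph nodes); columns are the ten features of
#' \code{\link{featureNames}}. Together with the unique id and the class
#' label this is the n x 12 node table from which the image graph is
#' built.
#'
#' @slot features numeric matrix, n x 10, columns named by featureNames()
#' @slot ids integer vector of unique node ids (1-based)
#' @slot labels character vector, "benign"/"malignant"
#' @export
setClass("FeatureTable", representation(
  features = "matrix",
  ids = "integer",
  labels = "character"
))

setValidity("FeatureTable", function(object) {
  msg <- NULL
  n <- nrow(object@features)
  if (ncol(object@features) != 10L ||
      !identical(colnames(object@features), featureNames()))
    msg <- c(msg, "features must be an n x 10 matrix with featureNames() columns")
  if (length(object@ids) != n || anyDuplicated(object@ids))
    msg <- c(msg, "ids must be unique and match the number of rows")
  if (length(object@labels) != n ||
      !all(object@labels %in% c("benign", "malignant")))
    msg <- c(msg, "labels must be 'benign'/'malignant', one per row")
  if (is.null(msg)) TRUE else msg
})

#' EdgeTable: weighted undirected edges of the image graph
#'
#' Each row is an unordered node pair (source < target) with its Spearman
#' correlation score. The unthresholded table over n nodes has
#' n(n-1)/2 rows.
#'
#' @slot edges data.frame with columns source, target, weight
#' @slot nNodes integer, number of nodes the edges refer to
#' @export
setClass("EdgeTable", representation(
  edges = "data.frame",
  nNodes = "integer"
))

setValidity("EdgeTable", function(object) {
  msg <- NULL
  e <- object@edges
  if (!all(c("source", "target", "weight") %in% names(e)))
    msg <- c(msg, "edges needs columns source, target, weight")
  else {
    if (nrow(e) > 0) {
      if (any(e$source >= e$target))
        msg <- c(msg, "edges must satisfy source < target")
      if (any(e$source < 1L | e$target > object@nNodes))
        msg <- c(msg, "node ids out of range")
      if (anyDuplicated(e[c("source", "target")]))
        msg <- c(msg, "duplicate node pairs")
      if (any(!is.finite(e$weight)) ||
          any(e$weight < -1 - 1e-9 | e$weight > 1 + 1e-9))
        msg <- c(msg, "weights must be finite Spearman scores in [-1, 1]")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' LesionGraph: the image graph fed to the classifier
#'
#' Bundles the node feature matrix X, node labels, the edge table E and
#' the binary adjacency A (symmetric, zero diagonal).
#'
#' @slot X numeric matrix, n x p node features
#' @slot labels character vector of node classes
#' @slot edgeTable EdgeTable
#' @slot adjacency binary adjacency matrix (base matrix for small graphs,
#'   Matrix::sparseMatrix above 2000 nodes; identical semantics)
#' @export
setClass("LesionGraph", representation(
  X = "matrix",
  labels = "character",
  edgeTable = "EdgeTable",
  adjacency = "ANY"
))

setValidity("LesionGraph", function(object) {
  msg <- NULL
  n <- nrow(object@X)
  A <- object@adjacency
  if (length(object@labels) != n)
    msg <- c(msg, "labels must match number of nodes")
  if (!is.null(A)) {
    if (nrow(A) != n || ncol(A) != n)
      msg <- c(msg, "adjacency must be n x n")
    else {
      if (any(Matrix::diag(A) != 0))
        msg <- c(msg, "adjacency must have zero diagonal")
      if (!Matrix::isSymmetric(A))
        msg <- c(msg, "adjacency must be symmetric")
    }
  }
  if (object@edgeTable@nNodes != n)
    msg <- c(msg, "edge table node count must match X")
  if (is.null(msg)) TRUE else msg
})

#' GNNConfig: hyperparameters of the graph classifier and training loop
#'
#' Defaults are the tuned operating point of the model: two 64-unit
#' hidden layers per feed-forward block, three graph-convolution layers,
#' nine feed-forward blocks, ELU activation, Nadam with learning rate
#' 0.01, batch size 128, dropout 0.2 inside blocks and 0.3 at model
#' level, the convolutional-recurrent skip combination, 100 epochs and
#' sparse categorical cross-entropy loss.
#'
#' @slot hiddenUnits integer pair, widths of the two dense layers per block
#' @slot nGcnLayers integer, number of message-passing layers
#' @slot nFfnBlocks integer, total feed-forward blocks (split around the
#'   graph-convolution stack)
#' @slot ffnDropout numeric in [0,1), dropout inside each block
#' @slot modelDropout numeric in [0,1), dropout before the output head
#' @slot activation "ELU", "ReLU" or "Tanh"
#' @slot optimizer "Nadam", "Adam", "Adamax" or "SGD"
#' @slot learningRate positive numeric
#' @slot batchSize positive integer (loss-node sampler; message passing is
#'   always full-graph)
#' @slot combinationType "conv_recurrent" or "concat"
#' @slot epochs positive integer
#' @slot aggregation "mean" or "sum" neighbor aggregation
#' @slot seed integer seed for init, dropout, batching
#' @export
setClass("GNNConfig", representation(
  hiddenUnits = "integer",
  nGcnLayers = "integer",
  nFfnBlocks = "integer",
  ffnDropout = "numeric",
  modelDropout = "numeric",
  activation = "character",
  optimizer = "character",
  learningRate = "numeric",
  batchSize = "integer",
  combinationType = "character",
  epochs = "integer",
  aggregation = "character",
  seed = "integer"
))

setValidity("GNNConfig", function(object) {
  msg <- NULL
  if (length(object@hiddenUnits) != 2L || any(object@hiddenUnits < 1L))
    msg <- c(msg, "hiddenUnits must be two positive integers")
  for (s in c("nGcnLayers", "nFfnBlocks", "batchSize", "epochs"))
    if (slot(object, s) < 1L) msg <- c(msg, paste(s, "must be positive"))
  for (s in c("ffnDropout", "modelDropout")) {
    r <- slot(object, s)
    if (r < 0 || r >= 1) msg <- c(msg, paste(s, "must be in [0, 1)"))
  }
  if (object@learningRate < 0)
    msg <- c(msg, "learningRate must be >= 0")
  if (!object@activation %in% c("ELU", "ReLU", "Tanh"))
    msg <- c(msg, "unknown activation")
  if (!object@optimizer %in% c("Nadam", "Adam", "Adamax", "SGD"))
    msg <- c(msg, "unknown optimizer")
  if (!object@combinationType %in% c("conv_recurrent", "concat"))
    msg <- c(msg, "unknown combinationType")
  if (!object@aggregation %in% c("mean", "sum"))
    msg <- c(msg, "unknown aggregation")
  if (is.null(msg)) TRUE else msg
})

#' GNNModel: a trained (or initialized) graph classifier
#'
#' @slot params named list of weight matrices
#' @slot buffers named list of batch-norm running statistics
#' @slot config GNNConfig used to build the model
#' @slot nFeatures integer input feature width
#' @export
setClass("GNNModel", representation(
  params = "list",
  buffers = "list",
  config = "GNNConfig",
  nFeatures = "integer"
))

#' EvalReport: confusion counts and the derived metric suite
#'
#' Metrics are percentages: accuracy, sensitivity (= recall on the
#' positive class), specificity, precision, NPV, FPR, FDR, FNR, F1 and
#' MCC. Identities FNR = 100 - sensitivity, FPR = 100 - specificity and
#' FDR = 100 - precision hold whenever the terms are defined. Metrics
#' with a zero denominator are NaN and listed in `undefined`.
#'
#' @slot confusion named integer vector TP, FP, TN, FN
#' @slot metrics named numeric vector of percentages
#' @slot undefined character vector of metrics with zero denominators
#' @export
setClass("EvalReport", representation(
  confusion = "integer",
  metrics = "numeric",
  undefined = "character"
))

#' FilterReport: bookkeeping of the edge-anomaly filter
#'
#' Counts of the two-branch removal flow: strong (>= strongCut) edges
#' joining distinct classes and weak (< weakCut) edges joining the same
#' class are removed; `intermediate` is the edge count after the strong
#' branch and `final = total - strongCrossRemoved - weakSameRemoved`.
#'
#' @slot counts named numeric: total, strong, strongCrossRemoved, weak,
#'   weakSameRemoved, intermediate, final
#' @export
setClass("FilterReport", representation(counts = "numeric"))

setValidity("FilterReport", function(object) {
  cnt <- object@counts
  need <- c("total", "strong", "strongCrossRemoved", "weak",
            "weakSameRemoved", "intermediate", "final")
  if (!all(need %in% names(cnt)))
    return("missing count fields")
  if (cnt["intermediate"] != cnt["total"] - cnt["strongCrossRemoved"])
    return("intermediate count inconsistent")
  if (cnt["final"] != cnt["total"] - cnt["strongCrossRemoved"] -
      cnt["weakSameRemoved"])
    return("final count inconsistent")
  TRUE
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %s, %dpx, irregularity=%.3g, spicules=%d, heterogeneity=%.3g, speckle=%.3g, rim=%.3g, seed=%d\n",
    object@classLabel, object@imageSize, object@boundaryIrregularity,
    object@nSpicules, object@textureHeterogeneity, object@speckleSigma,
    object@rimContrast, object@seed))
})

setMethod("show", "FeatureTable", function(object) {
  tab <- table(object@labels)
  cat(sprintf("FeatureTable: %d images x %d features (%s)\n",
              nrow(object@features), ncol(object@features),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "EdgeTable", function(object) {
  cat(sprintf("EdgeTable: %d edges over %d nodes\n",
              nrow(object@edges), object@nNodes))
})

setMethod("show", "LesionGraph", function(object) {
  cat(sprintf("LesionGraph: %d nodes, %d features, %d edges\n",
              nrow(object@X), ncol(object@X), nrow(object@edgeTable@edges)))
})

setMethod("show", "EvalReport", function(object) {
  cf <- object@confusion
  cat(sprintf("EvalReport: TP=%d FP=%d TN=%d FN=%d\n",
              cf["TP"], cf["FP"], cf["TN"], cf["FN"]))
  m <- object@metrics
  cat(paste(sprintf("  %s: %.2f", names(m), m), collapse = "\n"), "\n")
  if (length(object@undefined))
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
})

setMethod("show", "FilterReport", function(object) {
  cnt <- object@counts
  cat(sprintf(
    "FilterReport: total=%d strong=%d (-%d cross-class) weak=%d (-%d same-class) final=%d\n",
    cnt["total"], cnt["strong"], cnt["strongCrossRemoved"], cnt["weak"],
    cnt["weakSameRemoved"], cnt["final"]))
})
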