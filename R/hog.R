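#' HOG descriptor configuration
#'
#' Defaults: 224 x 224 input, 16 x 16-pixel cells, 2 x 2-cell blocks
#' with one-cell stride, 9 unsigned orientation bins — yielding the
#' 6084-long descriptor (13^2 blocks x 4 cells x 9 bins).
#'
#' @param imageSize square input side in pixels
#' @param cellSize cell side in pixels (must divide imageSize)
#' @param blockCells block side in cells
#' @param orientations number of orientation bins over [0, 180)
#' @return named list of settings
#' @export
hogConfig <- function(imageSize = 224L, cellSize = 16L, blockCells = 2L,
                      orientations = 9L) {
  cfg <- list(imageSize = as.integer(imageSize),
              cellSize = as.integer(cellSize),
              blockCells = as.integer(blockCells),
              orientations = as.integer(orientations))
  if (cfg$imageSize %% cfg$cellSize != 0L)
    stopf("config error: imageSize must be divisible by cellSize")
  if (cfg$blockCells > cfg$imageSize %/% cfg$cellSize)
    stopf("config error: block does not fit in the cell grid")
  cfg
}

#' Length of the HOG descriptor for a configuration
#'
#' (cellsPerSide - blockCells + 1)^2 x blockCells^2 x orientations;
#' depends only on the configuration, never on image content.
#'
#' @param config from \code{\link{hogConfig}}
#' @return integer descriptor length
#' @export
hogDescriptorLength <- function(config = hogConfig()) {
  nCells <- config$imageSize %/% config$cellSize
  nBlocks <- nCells - config$blockCells + 1L
  as.integer(nBlocks^2 * config$blockCells^2 * config$orientations)
}

#' Histogram-of-oriented-gradients descriptor of a full image
#'
#' Dense gradient-orientation descriptor: centered-difference
#' gradients, unsigned orientations in [0, 180) with bilinear voting
#' into 9 bins, 16 x 16-pixel cell histograms, 2 x 2-cell blocks with
#' one-cell stride and L2-Hys normalization (epsilon 1e-5, clip 0.2).
#' Images of a different size are resized bilinearly first. No mask is
#' used: the descriptor sees the whole image.
#'
#' @param image integer matrix of 8-bit intensities
#' @param config from \code{\link{hogConfig}}
#' @return numeric descriptor of \code{\link{hogDescriptorLength}} length
#' @export
hogFeatures <- function(image, config = hogConfig()) {
  s <- config$imageSize
  img <- image * 1.0
  if (!all(dim(img) == c(s, s)))
    img <- as.matrix(EBImage::resize(EBImage::Image(img), w = s, h = s))
  nr <- nrow(img); nc <- ncol(img)
  gx <- img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]
  gy <- img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  nb <- config$orientations
  bw <- pi / nb
  pos <- ang / bw - 0.5
  b0 <- floor(pos)
  frac <- pos - b0
  bin1 <- (b0 %% nb) + 1L
  bin2 <- ((b0 + 1) %% nb) + 1L
  w1 <- mag * (1 - frac)
  w2 <- mag * frac
  cs <- config$cellSize
  nCells <- s %/% cs
  cellRow <- (matrix(rep(seq_len(nr), nc), nr, nc) - 1L) %/% cs
  cellCol <- (matrix(rep(seq_len(nc), each = nr), nr, nc) - 1L) %/% cs
  cellIdx <- cellRow + nCells * cellCol  # 0-based cell index
  N <- nCells * nCells * nb
  accum <- function(bins, w) {
    idx <- cellIdx + nCells * nCells * (bins - 1L) + 1L
    out <- numeric(N)
    t <- rowsum(as.vector(w), as.vector(idx))
    out[as.integer(rownames(t))] <- t
    out
  }
  H <- array(accum(bin1, w1) + accum(bin2, w2), dim = c(nCells, nCells, nb))
  bc <- config$blockCells
  nBlocks <- nCells - bc + 1L
  eps <- 1e-5
  out <- numeric(0)
  for (bi in seq_len(nBlocks)) {
    for (bj in seq_len(nBlocks)) {
      v <- as.vector(H[bi:(bi + bc - 1L), bj:(bj + bc - 1L), ])
      v <- v / sqrt(sum(v^2) + eps^2)
      v <- pmin(v, 0.2)
      v <- v / sqrt(sum(v^2) + eps^2)
      out <- c(out, v)
    }
  }
  out
}

#' HOG feature table of a cohort
#'
#' One descriptor row per image (no masks involved), with the same id
#' and label layout as the handcrafted feature table.
#'
#' @param cohort list of image/mask/label triplets (masks ignored)
#' @param config from \code{\link{hogConfig}}
#' @return list with `features` (n x length matrix), `ids`, `labels`
#' @export
hogFeatureTable <- function(cohort, config = hogConfig()) {
  feats <- do.call(rbind, lapply(cohort, function(x)
    hogFeatures(x$image, config)))
  list(features = feats, ids = seq_along(cohort),
       labels = vapply(cohort, function(x) x$label, character(1)))
}

#' HOG comparison arm: descriptor graph plus the identical GNN
#'
#' Builds the Spearman edge table over HOG descriptor rows (no
#' threshold by default), assembles the graph with the descriptors as
#' node features, and trains the same classifier with the same seed.
#'
#' @param cohort list of image/mask/label triplets
#' @param config a \linkS4class{GNNConfig}
#' @param hogCfg from \code{\link{hogConfig}}
#' @param tau optional correlation threshold
#' @return list with `report` (\linkS4class{EvalReport}), `graph`, `fit`
#' @export
hogGraphPipeline <- function(cohort, config = gnnConfig(),
                             hogCfg = hogConfig(), tau = NULL) {
  ht <- hogFeatureTable(cohort, hogCfg)
  et <- buildEdgeTable(ht$features)
  et <- thresholdEdges(et, tau)
  g <- new("LesionGraph", X = ht$features, labels = ht$labels,
           edgeTable = et, adjacency = toAdjacency(et))
  fit <- trainGNN(g, config)
  list(report = fit$report, graph = g, fit = fit)
}

#' Side-by-side comparison of the handcrafted and HOG arms
#'
#' Runs the handcrafted-feature pipeline (masks, ten features,
#' optional threshold) and the HOG pipeline (full image, no masks) on
#' the same cohort with the same classifier seed, and reports both
#' accuracies and their difference.
#'
#' @param cohort list of image/mask/label triplets
#' @param config a \linkS4class{GNNConfig}
#' @param tau threshold for the handcrafted arm (HOG arm runs
#'   unthresholded, its reference comparison)
#' @return list with `handcrafted`, `hog` (EvalReports) and
#'   `accuracyDifference` (handcrafted minus HOG, percentage points)
#' @export
compareArms <- function(cohort, config = gnnConfig(), tau = NULL) {
  ft <- buildFeatureTable(cohort)
  g <- buildGraph(ft, tau = tau)
  handFit <- trainGNN(g, config)
  hogFit <- hogGraphPipeline(cohort, config)
  diffAcc <- unname(metricValues(handFit$report)["accuracy"] -
                      metricValues(hogFit$report)["accuracy"])
  list(handcrafted = handFit$report, hog = hogFit$report,
       accuracyDifference = diffAcc)
}
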