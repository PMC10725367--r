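#' Construct a GNNConfig
#'
#' Defaults are the tuned operating point: see \linkS4class{GNNConfig}.
#'
#' @param hiddenUnits widths of the two dense layers per block
#' @param nGcnLayers number of graph-convolution layers
#' @param nFfnBlocks total feed-forward blocks
#' @param ffnDropout dropout inside blocks
#' @param modelDropout dropout before the output head
#' @param activation "ELU", "ReLU" or "Tanh"
#' @param optimizer "Nadam", "Adam", "Adamax" or "SGD"
#' @param learningRate learning rate
#' @param batchSize loss-node batch size
#' @param combinationType "conv_recurrent" or "concat"
#' @param epochs training epochs
#' @param aggregation "mean" or "sum" neighbor aggregation
#' @param seed seed for init, dropout and batching
#' @return validated \linkS4class{GNNConfig}
#' @export
gnnConfig <- function(hiddenUnits = c(64L, 64L), nGcnLayers = 3L,
                      nFfnBlocks = 9L, ffnDropout = 0.2,
                      modelDropout = 0.3, activation = "ELU",
                      optimizer = "Nadam", learningRate = 0.01,
                      batchSize = 128L, combinationType = "conv_recurrent",
                      epochs = 100L, aggregation = "mean", seed = 1L) {
  new("GNNConfig", hiddenUnits = as.integer(hiddenUnits),
      nGcnLayers = as.integer(nGcnLayers),
      nFfnBlocks = as.integer(nFfnBlocks),
      ffnDropout = as.numeric(ffnDropout),
      modelDropout = as.numeric(modelDropout),
      activation = activation, optimizer = optimizer,
      learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize),
      combinationType = combinationType, epochs = as.integer(epochs),
      aggregation = aggregation, seed = as.integer(seed))
}

# blocks are split around the GCN stack: ceiling(n/2) before, rest after
splitBlocks <- function(cfg) {
  nPre <- as.integer(ceiling(cfg@nFfnBlocks / 2))
  c(pre = nPre, post = cfg@nFfnBlocks - nPre)
}

initGnnParams <- function(cfg, nFeatures) {
  h <- cfg@hiddenUnits
  d <- h[2]
  sp <- splitBlocks(cfg)
  params <- list(pre = list(), gcn = list(), comb = NULL, post = list(),
                 head = NULL)
  buffers <- list(pre = list(), post = list())
  nIn <- nFeatures
  for (i in seq_len(sp["pre"])) {
    params$pre[[i]] <- initFfnBlock(nIn, h)
    buffers$pre[[i]] <- emptyBnBuf(nIn)
    nIn <- d
  }
  for (j in seq_len(cfg@nGcnLayers)) params$gcn[[j]] <- initGcn(d)
  params$comb <- initCombiner(d, cfg@combinationType)
  for (i in seq_len(sp["post"])) {
    params$post[[i]] <- initFfnBlock(d, h)
    buffers$post[[i]] <- emptyBnBuf(d)
  }
  params$head <- list(W = glorot(d, 2L), b = rep(0, 2L))
  list(params = params, buffers = buffers)
}

gnnForwardFull <- function(params, buffers, X, Anorm, cfg, training) {
  act <- actFun(cfg@activation)
  caches <- list(pre = list(), gcn = list(), post = list())
  h <- X
  for (i in seq_along(params$pre)) {
    r <- ffnBlockFwd(h, params$pre[[i]], buffers$pre[[i]], act,
                     cfg@ffnDropout, training)
    h <- r$out; buffers$pre[[i]] <- r$buf; caches$pre[[i]] <- r$cache
  }
  skip0 <- h
  for (j in seq_along(params$gcn)) {
    r <- gcnFwd(h, Anorm, params$gcn[[j]], act, normalize = TRUE)
    h <- r$out; caches$gcn[[j]] <- r$cache
  }
  r <- combFwd(skip0, h, params$comb, act, cfg@combinationType)
  h <- r$out; caches$comb <- r$cache
  for (i in seq_along(params$post)) {
    r <- ffnBlockFwd(h, params$post[[i]], buffers$post[[i]], act,
                     cfg@ffnDropout, training)
    h <- r$out; buffers$post[[i]] <- r$buf; caches$post[[i]] <- r$cache
  }
  dp <- dropoutFwd(h, cfg@modelDropout, training)
  caches$modelMask <- dp$mask
  hd <- denseFwd(dp$out, params$head$W, params$head$b)
  caches$head <- hd
  logits <- hd$out
  list(logits = logits, probs = softmaxRows(logits), caches = caches,
       buffers = buffers)
}

gnnBackwardFull <- function(params, caches, dLogits, Anorm, cfg) {
  act <- actFun(cfg@activation)
  grads <- list(pre = list(), gcn = list(), comb = NULL, post = list(),
                head = NULL)
  hg <- denseBwd(dLogits, caches$head, params$head$W)
  grads$head <- list(W = hg$dW, b = hg$db)
  dh <- dropoutBwd(hg$dX, caches$modelMask)
  for (i in rev(seq_along(params$post))) {
    r <- ffnBlockBwd(dh, params$post[[i]], caches$post[[i]], act)
    grads$post[[i]] <- r$grads; dh <- r$dX
  }
  cb <- combBwd(dh, params$comb, caches$comb, act)
  grads$comb <- cb$grads
  dh <- cb$dG
  for (j in rev(seq_along(params$gcn))) {
    r <- gcnBwd(dh, params$gcn[[j]], caches$gcn[[j]], Anorm, act)
    grads$gcn[[j]] <- r$grads; dh <- r$dX
  }
  dh <- dh + cb$dSkip  # skip path into the combiner
  for (i in rev(seq_along(params$pre))) {
    r <- ffnBlockBwd(dh, params$pre[[i]], caches$pre[[i]], act)
    grads$pre[[i]] <- r$grads; dh <- r$dX
  }
  grads
}

#' Class probabilities of a graph under a model
#'
#' Inference-mode forward pass: running batch-norm statistics, no
#' dropout. Rows sum to 1.
#'
#' @param model a \linkS4class{GNNModel}
#' @param graph a \linkS4class{LesionGraph}
#' @return n x 2 matrix of probabilities (columns benign, malignant)
#' @export
gnnForward <- function(model, graph) {
  X <- nodeFeatures(graph)
  if (ncol(X) != model@nFeatures)
    stopf("dimension error: graph has %d features, model expects %d",
          ncol(X), model@nFeatures)
  Anorm <- normalizeAdjacency(adjacency(graph), model@config@aggregation)
  out <- gnnForwardFull(model@params, model@buffers, X, Anorm,
                        model@config, training = FALSE)
  colnames(out$probs) <- c("benign", "malignant")
  out$probs
}

#' Predicted class labels of a graph
#'
#' @inheritParams gnnForward
#' @return character vector of "benign"/"malignant"
#' @export
gnnPredict <- function(model, graph) {
  p <- gnnForward(model, graph)
  ifelse(p[, "malignant"] > p[, "benign"], "malignant", "benign")
}

#' Train the graph classifier transductively
#'
#' Message passing always sees the full adjacency; the loss (sparse
#' categorical cross-entropy) is computed on mini-batches of training
#' nodes only. Deterministic under a fixed config seed.
#'
#' @param graph a \linkS4class{LesionGraph}
#' @param config a \linkS4class{GNNConfig}
#' @param split optional list with integer index vectors train, val,
#'   test; default is a stratified 80/10/10 split from the config seed
#' @return list with `model` (\linkS4class{GNNModel}), `report`
#'   (\linkS4class{EvalReport} on the test nodes), `curves` (per-epoch
#'   loss/accuracy data.frame) and `split`
#' @export
trainGNN <- function(graph, config = gnnConfig(), split = NULL) {
  labels <- nodeLabels(graph)
  y <- as.integer(labels == "malignant")
  if (is.null(split))
    split <- stratifiedSplit(labels, c(train = 0.8, val = 0.1, test = 0.1),
                             seed = config@seed)
  for (s in c("train", "val", "test"))
    if (length(split[[s]]) < 1L)
      stopf("degenerate-split error: empty %s set", s)
  if (length(unique(y[split$train])) < 2L)
    stopf("degenerate-split error: training set has a single class")
  X <- nodeFeatures(graph)
  Anorm <- normalizeAdjacency(adjacency(graph), config@aggregation)
  nTrain <- length(split$train)

  curves <- data.frame(epoch = seq_len(config@epochs),
                       train_loss = NA_real_,
                       train_accuracy = NA_real_,
                       val_accuracy = NA_real_)
  state <- withSeed(config@seed, {
    init <- initGnnParams(config, ncol(X))
    params <- init$params
    buffers <- init$buffers
    opt <- makeOptimizer(config@optimizer, config@learningRate)
    for (ep in seq_len(config@epochs)) {
      perm <- sample(split$train)
      starts <- seq(1L, nTrain, by = config@batchSize)
      losses <- numeric(0)
      for (st in starts) {
        batch <- perm[st:min(st + config@batchSize - 1L, nTrain)]
        fw <- gnnForwardFull(params, buffers, X, Anorm, config,
                             training = TRUE)
        buffers <- fw$buffers
        p <- fw$probs
        losses <- c(losses,
                    -mean(log(pmax(p[cbind(batch, y[batch] + 1L)], 1e-12))))
        dL <- matrix(0, nrow(X), 2L)
        dL[batch, ] <- p[batch, , drop = FALSE]
        dL[cbind(batch, y[batch] + 1L)] <-
          dL[cbind(batch, y[batch] + 1L)] - 1
        dL[batch, ] <- dL[batch, ] / length(batch)
        grads <- gnnBackwardFull(params, fw$caches, dL, Anorm, config)
        params <- opt$step(params, grads)
      }
      ev <- gnnForwardFull(params, buffers, X, Anorm, config,
                           training = FALSE)
      pred <- max.col(ev$probs) - 1L
      curves$train_loss[ep] <- mean(losses)
      curves$train_accuracy[ep] <- mean(pred[split$train] == y[split$train])
      curves$val_accuracy[ep] <- mean(pred[split$val] == y[split$val])
    }
    list(params = params, buffers = buffers)
  })
  model <- new("GNNModel", params = state$params, buffers = state$buffers,
               config = config, nFeatures = ncol(X))
  pred <- gnnPredict(model, graph)
  report <- evaluateClassifier(pred[split$test], labels[split$test])
  list(model = model, report = report, curves = curves, split = split)
}

#' Confusion-matrix metric suite for binary predictions
#'
#' Positive class is malignant. Metrics are percentages; any metric
#' with a zero denominator is NaN and flagged in the report's
#' `undefined` slot rather than silently set to 0.
#'
#' @param predicted character vector of predicted labels
#' @param actual character vector of true labels
#' @param positive the positive class label
#' @return an \linkS4class{EvalReport}
#' @export
evaluateClassifier <- function(predicted, actual,
                               positive = "malignant") {
  if (length(predicted) != length(actual))
    stopf("dimension error: prediction and label lengths differ")
  pp <- predicted == positive
  ap <- actual == positive
  TP <- sum(pp & ap); FP <- sum(pp & !ap)
  TN <- sum(!pp & !ap); FN <- sum(!pp & ap)
  rat <- function(num, den) if (den == 0) NaN else 100 * num / den
  sens <- rat(TP, TP + FN)
  spec <- rat(TN, TN + FP)
  prec <- rat(TP, TP + FP)
  npv <- rat(TN, TN + FN)
  f1 <- if (is.nan(prec) || is.nan(sens) || prec + sens == 0) NaN else
    2 * prec * sens / (prec + sens)
  mccDen <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mccDen == 0) NaN else
    100 * (TP * TN - FP * FN) / mccDen
  metrics <- c(accuracy = rat(TP + TN, TP + TN + FP + FN),
               sensitivity = sens, recall = sens, specificity = spec,
               precision = prec, npv = npv,
               fpr = 100 - spec, fdr = 100 - prec, fnr = 100 - sens,
               f1 = f1, mcc = mcc)
  new("EvalReport",
      confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
      metrics = metrics,
      undefined = names(metrics)[is.nan(metrics)])
}

#' F1 score from precision and recall percentages
#'
#' Harmonic mean 2 p r / (p + r), in percent.
#'
#' @param precision,recall percentages
#' @return F1 in percent
#' @export
f1Score <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' Accuracy/edge-count sweep over correlation thresholds
#'
#' Re-thresholds the same unthresholded edge table at each tau and
#' retrains with an identical split and seed for comparability.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param taus list of thresholds (NULL entries mean no threshold)
#' @param config a \linkS4class{GNNConfig}
#' @return data.frame with threshold (NA for none), edges, accuracy
#' @export
thresholdSweep <- function(table, taus, config = gnnConfig()) {
  et <- buildEdgeTable(table)
  labels <- nodeLabels(table)
  split <- stratifiedSplit(labels, c(train = 0.8, val = 0.1, test = 0.1),
                           seed = config@seed)
  rows <- lapply(taus, function(tau) {
    sub <- thresholdEdges(et, tau)
    g <- new("LesionGraph", X = nodeFeatures(table), labels = labels,
             edgeTable = sub, adjacency = toAdjacency(sub))
    fit <- trainGNN(g, config, split = split)
    data.frame(threshold = if (is.null(tau)) NA_real_ else tau,
               edges = nrow(sub@edges),
               accuracy = unname(metricValues(fit$report)["accuracy"]))
  })
  do.call(rbind, rows)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Each fold serves once as the test set; 10% of the remaining nodes
#' are held out for validation. The reported mean is the arithmetic
#' mean of the fold accuracies.
#'
#' @param graph a \linkS4class{LesionGraph}
#' @param k number of folds (>= 2, at most the minority class count)
#' @param config a \linkS4class{GNNConfig}
#' @return list with foldAccuracy, mean, sd
#' @export
kfoldCV <- function(graph, k = 5L, config = gnnConfig()) {
  if (k < 2L) stopf("fold error: k must be >= 2")
  labels <- nodeLabels(graph)
  folds <- stratifiedFolds(labels, k, seed = config@seed)
  accs <- vapply(seq_len(k), function(f) {
    testIdx <- folds[[f]]
    rest <- setdiff(seq_along(labels), testIdx)
    sub <- stratifiedSplit(labels[rest], c(train = 0.9, val = 0.1),
                           seed = config@seed + f)
    split <- list(train = rest[sub$train], val = rest[sub$val],
                  test = testIdx)
    fit <- trainGNN(graph, config, split = split)
    unname(metricValues(fit$report)["accuracy"]) / 100
  }, numeric(1))
  list(foldAccuracy = accs, mean = mean(accs), sd = stats::sd(accs))
}
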