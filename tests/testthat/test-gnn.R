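test_that("feed-forward block output is the dense path plus the skip", {
  set.seed(2)
  X <- matrix(rnorm(12 * 10), 12, 10)
  p <- initFfnBlockParams(10L, c(64L, 64L), seed = 5L)
  # inference with unit batch-norm buffers reduces BN to near-identity
  out <- ffnBlock(X, p, activation = "ELU", dropout = 0.2,
                  training = FALSE)$out
  elu <- function(z) ifelse(z > 0, z, exp(z) - 1)
  eps <- 1e-5
  xhat <- X / sqrt(1 + eps)
  path <- elu(elu(xhat %*% p$W1 + matrix(p$b1, 12, 64, byrow = TRUE)) %*%
                p$W2 + matrix(p$b2, 12, 64, byrow = TRUE))
  expect_equal(out, path + X %*% p$Wskip, tolerance = 1e-9)
  expect_equal(dim(out), c(12L, 64L))
  # width-64 input skips without projection
  p64 <- initFfnBlockParams(64L, c(64L, 64L), seed = 5L)
  expect_null(p64$Wskip)
  expect_equal(dim(ffnBlock(matrix(rnorm(5 * 64), 5, 64), p64)$out),
               c(5L, 64L))
  expect_error(ffnBlock(matrix(0, 3, 7), p), "dimension")
})

test_that("training and inference agree when dropout is off and stats match", {
  set.seed(3)
  X <- matrix(rnorm(20 * 10), 20, 10)
  p <- initFfnBlockParams(10L, c(64L, 64L), seed = 9L)
  # momentum 0 copies the batch statistics into the running buffers
  tr <- ffnBlock(X, p, activation = "ELU", dropout = 0,
                 training = TRUE, momentum = 0)
  inf <- ffnBlock(X, p, buffers = tr$buffers, activation = "ELU",
                  dropout = 0, training = FALSE)
  expect_equal(tr$out, inf$out, tolerance = 1e-9)
})

test_that("message passing matches hand evaluation and a per-node oracle", {
  # isolated node: neighbor term vanishes
  H <- matrix(c(1, 2, 3, 4), 2, 2)
  A0 <- matrix(0, 2, 2)
  Wn <- diag(2); Wnei <- diag(2)
  out0 <- messagePass(H, A0, Wn, Wnei, activation = "identity")
  expect_equal(out0, H)
  # 2-node path with identity weights and sum aggregation
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  out <- messagePass(H, A, Wn, Wnei, aggregate = "sum",
                     activation = "identity")
  expect_equal(out[1, ], H[1, ] + H[2, ])
  expect_equal(out[2, ], H[1, ] + H[2, ])
  expect_error(messagePass(H, matrix(c(0, 1, 0, 0), 2, 2), Wn, Wnei),
               "adjacency")
  # random graph against a naive double loop
  set.seed(7)
  n <- 9; d <- 5
  H <- matrix(rnorm(n * d), n, d)
  A <- matrix(0, n, n)
  for (k in 1:12) { ij <- sample(n, 2); A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- 1 }
  diag(A) <- 0
  Wn <- matrix(rnorm(d * d), d, d); Wnei <- matrix(rnorm(d * d), d, d)
  b <- rnorm(d)
  for (mode in c("sum", "mean")) {
    ref <- matrix(0, n, d)
    for (u in 1:n) {
      nb <- which(A[u, ] == 1)
      agg <- if (length(nb) == 0) rep(0, d) else colSums(H[nb, , drop = FALSE])
      if (mode == "mean" && length(nb) > 0) agg <- agg / length(nb)
      z <- H[u, ] %*% Wn + agg %*% Wnei + b
      ref[u, ] <- ifelse(z > 0, z, exp(z) - 1)
    }
    got <- messagePass(H, A, Wn, Wnei, b, activation = "ELU",
                       aggregate = mode)
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("forward pass is a softmax and is permutation-equivariant", {
  ft <- fixtureFeatureTable()
  g <- buildGraph(ft, tau = 0.9)
  cfg <- gnnConfig(epochs = 2L, seed = 5L, batchSize = 16L)
  fit <- trainGNN(g, cfg)
  p <- gnnForward(fit$model, g)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(unname(rowSums(p)), rep(1, nNodes(g)), tolerance = 1e-6)
  # zero output head gives the uninformative posterior
  m0 <- fit$model
  m0@params$head$W[] <- 0
  m0@params$head$b[] <- 0
  p0 <- gnnForward(m0, g)
  expect_equal(unname(p0), matrix(0.5, nNodes(g), 2))
  # consistent node permutation permutes the outputs identically
  set.seed(8)
  perm <- sample(nNodes(g))
  gp <- new("LesionGraph", X = nodeFeatures(g)[perm, ],
            labels = nodeLabels(g)[perm],
            edgeTable = new("EdgeTable",
                            edges = data.frame(source = integer(0),
                                               target = integer(0),
                                               weight = numeric(0)),
                            nNodes = nNodes(g)),
            adjacency = adjacency(g)[perm, perm])
  pp <- gnnForward(fit$model, gp)
  expect_equal(pp, p[perm, ], tolerance = 1e-10)
})

test_that("analytic gradients match finite differences", {
  cfg <- gnnConfig(hiddenUnits = c(5L, 5L), nGcnLayers = 2L,
                   nFfnBlocks = 3L, ffnDropout = 0, modelDropout = 0,
                   epochs = 1L, seed = 3L)
  set.seed(42)
  n <- 7; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  A <- matrix(0, n, n)
  for (k in 1:8) { ij <- sample(n, 2); A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- 1 }
  diag(A) <- 0
  y <- sample(0:1, n, replace = TRUE)
  Anorm <- SonoGraph:::normalizeAdjacency(A, "mean")
  init <- SonoGraph:::initGnnParams(cfg, p)
  lossOf <- function(par) {
    fw <- SonoGraph:::gnnForwardFull(par, init$buffers, X, Anorm, cfg,
                                     training = TRUE)
    -mean(log(fw$probs[cbind(1:n, y + 1)]))
  }
  fw <- SonoGraph:::gnnForwardFull(init$params, init$buffers, X, Anorm,
                                   cfg, training = TRUE)
  dL <- fw$probs
  dL[cbind(1:n, y + 1)] <- dL[cbind(1:n, y + 1)] - 1
  dL <- dL / n
  grads <- SonoGraph:::gnnBackwardFull(init$params, fw$caches, dL, Anorm,
                                       cfg)
  paths <- list(list("pre", 1L, "W1"), list("pre", 1L, "gamma"),
                list("pre", 2L, "beta"), list("gcn", 1L, "Wn"),
                list("gcn", 2L, "Wnei"), list("comb", "U"),
                list("comb", "V"), list("post", 1L, "W2"),
                list("head", "W"))
  for (path in paths) {
    gnode <- grads; pnode <- init$params
    for (k in path) { gnode <- gnode[[k]]; pnode <- pnode[[k]] }
    for (i in sample(length(pnode), 3)) {
      eps <- 1e-5
      bump <- function(delta) {
        q <- init$params
        if (length(path) == 2) {
          q[[path[[1]]]][[path[[2]]]][i] <-
            q[[path[[1]]]][[path[[2]]]][i] + delta
        } else {
          q[[path[[1]]]][[path[[2]]]][[path[[3]]]][i] <-
            q[[path[[1]]]][[path[[2]]]][[path[[3]]]][i] + delta
        }
        q
      }
      num <- (lossOf(bump(eps)) - lossOf(bump(-eps))) / (2 * eps)
      expect_equal(gnode[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is seeded-deterministic and frozen at zero learning rate", {
  ft <- fixtureFeatureTable()
  g <- buildGraph(ft, tau = 0.9)
  cfg0 <- gnnConfig(epochs = 3L, learningRate = 0, seed = 6L,
                    batchSize = 16L)
  fit0 <- trainGNN(g, cfg0)
  ref <- withr::with_seed(6L, SonoGraph:::initGnnParams(cfg0, 10L))
  expect_equal(unname(fit0$model@params$head$W), unname(ref$params$head$W),
               tolerance = 1e-12)
  expect_equal(unname(fit0$model@params$pre[[1]]$W1),
               unname(ref$params$pre[[1]]$W1), tolerance = 1e-12)
  cfg <- gnnConfig(epochs = 3L, seed = 6L, batchSize = 16L)
  a <- trainGNN(g, cfg)
  b <- trainGNN(g, cfg)
  expect_identical(a$curves, b$curves)
  expect_equal(a$model@params$head$W, b$model@params$head$W,
               tolerance = 1e-15)
  # degenerate splits are refused
  lab <- nodeLabels(g)
  badSplit <- list(train = which(lab == "benign"),
                   val = which(lab == "malignant")[1:3],
                   test = which(lab == "malignant")[4:6])
  expect_error(trainGNN(g, cfg, split = badSplit), "degenerate-split")
})

test_that("the classifier recovers the classes on a separable cohort graph", {
  ft <- fixtureFeatureTable()
  g <- buildGraph(ft, tau = 0.95)
  cfg <- gnnConfig(epochs = 60L, seed = 1L, batchSize = 48L)
  fit <- trainGNN(g, cfg)
  expect_gte(metricValues(fit$report)[["accuracy"]], 90)
  expect_equal(nrow(fit$curves), 60L)
  expect_true(all(is.finite(fit$curves$train_loss)))
})

test_that("evaluation metrics satisfy their confusion-matrix identities", {
  lab <- c(rep("malignant", 5), rep("benign", 5))
  perfect <- evaluateClassifier(lab, lab)
  m <- metricValues(perfect)
  expect_equal(unname(m[c("accuracy", "precision", "recall",
                          "specificity", "mcc", "f1")]),
               rep(100, 6))
  expect_equal(unname(m[c("fpr", "fdr", "fnr")]), rep(0, 3))
  # printed-precision F1 identity
  expect_equal(round(f1Score(100, 98.57), 2), 99.28)
  # direct formula oracle for a fixed confusion matrix
  pred <- c(rep("malignant", 69), rep("benign", 1 + 122))
  act <- c(rep("malignant", 70), rep("benign", 122))
  r <- evaluateClassifier(pred, act)
  expect_equal(unname(confusionCounts(r)), c(69L, 0L, 122L, 1L))
  mm <- metricValues(r)
  expect_equal(round(unname(mm["sensitivity"]), 2), 98.57)
  expect_equal(round(unname(mm["npv"]), 2), 99.19)
  expect_equal(unname(mm["specificity"]), 100)
  # identities on random confusion matrices
  for (s in 1:25) {
    set.seed(s)
    act <- sample(c("benign", "malignant"), 40, replace = TRUE)
    pred <- sample(c("benign", "malignant"), 40, replace = TRUE)
    r <- evaluateClassifier(pred, act)
    cf <- confusionCounts(r)
    mv <- metricValues(r)
    expect_equal(sum(cf), 40L)
    if (!is.nan(mv["sensitivity"]))
      expect_equal(unname(mv["fnr"]), 100 - unname(mv["sensitivity"]))
    if (!is.nan(mv["specificity"]))
      expect_equal(unname(mv["fpr"]), 100 - unname(mv["specificity"]))
    if (!is.nan(mv["precision"]))
      expect_equal(unname(mv["fdr"]), 100 - unname(mv["precision"]))
  }
  # zero denominators surface as flagged NaN, never silent zeros
  allNeg <- evaluateClassifier(rep("benign", 4), rep("benign", 4))
  expect_true("precision" %in% allNeg@undefined)
  expect_true(is.nan(metricValues(allNeg)["sensitivity"]))
})

test_that("threshold sweep reuses the split and shrinks edge counts", {
  ft <- fixtureFeatureTable()
  cfg <- gnnConfig(epochs = 3L, seed = 2L, batchSize = 16L)
  sw <- thresholdSweep(ft, list(NULL, 0.9, 0.97), cfg)
  expect_equal(nrow(sw), 3L)
  expect_equal(sw$edges[1], 60 * 59 / 2)
  expect_true(all(diff(sw$edges) <= 0))
  expect_true(is.na(sw$threshold[1]))
})

test_that("k-fold cross-validation is stratified and internally consistent", {
  ft <- fixtureFeatureTable()
  g <- buildGraph(ft, tau = 0.9)
  cfg <- gnnConfig(epochs = 3L, seed = 4L, batchSize = 16L)
  cv <- kfoldCV(g, k = 3L, config = cfg)
  expect_length(cv$foldAccuracy, 3L)
  expect_equal(cv$mean, mean(cv$foldAccuracy), tolerance = 1e-12)
  expect_error(kfoldCV(g, k = 1L, config = cfg), "fold error")
  expect_error(kfoldCV(g, k = 40L, config = cfg), "fold error")
})

test_that("Bayesian tuning respects bounds and finds a known optimum", {
  # one-point space returns immediately after a single evaluation
  space1 <- list(x = list(lower = 0.3, upper = 0.3, integer = FALSE))
  calls <- 0L
  r1 <- tuneBayesian(function(p) { calls <<- calls + 1L; -p$x },
                     space1, budget = 5L, seed = 1L)
  expect_equal(r1$best$x, 0.3)
  expect_equal(calls, 1L)
  # deterministic quadratic over a scaled domain
  space <- list(x = list(lower = 0, upper = 1, integer = FALSE))
  r <- tuneBayesian(function(p) -(p$x - 0.7)^2, space, budget = 25L,
                    seed = 3L)
  expect_lt(abs(r$best$x - 0.7), 0.05)
  expect_equal(nrow(r$trials), 25L)
  # every proposal of the default space satisfies its bounds
  rs <- tuneBayesian(function(p) p$learningRate * p$dropout,
                     tuningSpace(), budget = 12L, seed = 5L)
  tr <- rs$trials
  expect_true(all(tr$hiddenUnits >= 32 & tr$hiddenUnits <= 64))
  expect_true(all(tr$hiddenUnits == round(tr$hiddenUnits)))
  expect_true(all(tr$learningRate >= 0.001 & tr$learningRate <= 0.01))
  expect_true(all(tr$batchSize >= 64 & tr$batchSize <= 128))
  expect_true(all(tr$dropout >= 0.3 & tr$dropout <= 0.7))
  expect_error(tuneBayesian(function(p) 1, list(), budget = 3L),
               "empty")
})
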