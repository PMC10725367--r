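# neural-network primitives: forward/backward pairs with explicit caches.
# All matrices are nodes x features; gradients follow reverse order.

actFun <- function(name) {
  switch(name,
    ELU = list(
      f = function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
      # derivative in terms of input x and output y: 1 for x>0, y+1 below
      d = function(x, y) ifelse(x > 0, 1, y + 1)),
    ReLU = list(
      f = function(x) pmax(x, 0),
      d = function(x, y) (x > 0) * 1),
    Tanh = list(
      f = function(x) tanh(x),
      d = function(x, y) 1 - y^2),
    identity = list(f = function(x) x, d = function(x, y) 1),
    stopf("unknown activation '%s'", name))
}

rowRep <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

denseFwd <- function(X, W, b) {
  list(out = X %*% W + rowRep(b, nrow(X)), X = X)
}

denseBwd <- function(dY, cache, W) {
  list(dW = crossprod(cache$X, dY), db = colSums(dY),
       dX = tcrossprod(dY, W))
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

bnFwd <- function(X, gamma, beta, buf, training, momentum = 0.9,
                  eps = 1e-5) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    va <- colMeans(X^2) - mu^2
    buf$mean <- momentum * buf$mean + (1 - momentum) * mu
    buf$var <- momentum * buf$var + (1 - momentum) * va
  } else {
    mu <- buf$mean; va <- buf$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(X, 2, mu), 2, istd, `*`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, buf = buf,
       cache = list(xhat = xhat, istd = istd, training = training))
}

bnBwd <- function(dY, cache, gamma) {
  xhat <- cache$xhat; istd <- cache$istd
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, `*`)
  if (cache$training) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dX <- sweep(dxhat - rowRep(m1, nrow(dY)) -
                  xhat * rowRep(m2, nrow(dY)), 2, istd, `*`)
  } else {
    dX <- sweep(dxhat, 2, istd, `*`)
  }
  list(dgamma = dgamma, dbeta = dbeta, dX = dX)
}

dropoutFwd <- function(X, rate, training) {
  if (!training || rate <= 0)
    return(list(out = X, mask = NULL))
  keep <- 1 - rate
  mask <- (matrix(stats::runif(length(X)), nrow(X), ncol(X)) < keep) / keep
  list(out = X * mask, mask = mask)
}

dropoutBwd <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# ---- feed-forward block: BN -> dropout -> dense -> act -> dense -> act,
# with an additive skip connection (linear projection on width change)

initFfnBlock <- function(nIn, hidden) {
  p <- list(gamma = rep(1, nIn), beta = rep(0, nIn),
            W1 = glorot(nIn, hidden[1]), b1 = rep(0, hidden[1]),
            W2 = glorot(hidden[1], hidden[2]), b2 = rep(0, hidden[2]))
  if (nIn != hidden[2]) p$Wskip <- glorot(nIn, hidden[2])
  p
}

emptyBnBuf <- function(d) list(mean = rep(0, d), var = rep(1, d))

ffnBlockFwd <- function(X, p, buf, act, dropout, training,
                        momentum = 0.9) {
  bn <- bnFwd(X, p$gamma, p$beta, buf, training, momentum)
  dp <- dropoutFwd(bn$out, dropout, training)
  d1 <- denseFwd(dp$out, p$W1, p$b1)
  a1 <- act$f(d1$out)
  d2 <- denseFwd(a1, p$W2, p$b2)
  a2 <- act$f(d2$out)
  skip <- if (is.null(p$Wskip)) X else X %*% p$Wskip
  list(out = a2 + skip, buf = bn$buf,
       cache = list(X = X, bn = bn$cache, mask = dp$mask, d1 = d1,
                    z1 = d1$out, a1 = a1, d2 = d2, z2 = d2$out, a2 = a2))
}

ffnBlockBwd <- function(dY, p, cache, act) {
  g <- list()
  dA2 <- dY
  dZ2 <- dA2 * act$d(cache$z2, cache$a2)
  b2g <- denseBwd(dZ2, cache$d2, p$W2)
  g$W2 <- b2g$dW; g$b2 <- b2g$db
  dZ1 <- b2g$dX * act$d(cache$z1, cache$a1)
  b1g <- denseBwd(dZ1, cache$d1, p$W1)
  g$W1 <- b1g$dW; g$b1 <- b1g$db
  dBn <- dropoutBwd(b1g$dX, cache$mask)
  bng <- bnBwd(dBn, cache$bn, p$gamma)
  g$gamma <- bng$dgamma; g$beta <- bng$dbeta
  dX <- bng$dX
  if (is.null(p$Wskip)) {
    dX <- dX + dY
  } else {
    g$Wskip <- crossprod(cache$X, dY)
    dX <- dX + tcrossprod(dY, p$Wskip)
  }
  list(grads = g, dX = dX)
}

# ---- graph convolution: Z = H Wn + (Anorm H) Wnei + b, sigma, then
# row-wise L2 normalization of the embeddings

initGcn <- function(d) {
  list(Wn = glorot(d, d), Wnei = glorot(d, d), b = rep(0, d))
}

gcnFwd <- function(H, Anorm, p, act, normalize = TRUE) {
  M <- Anorm %*% H
  Z <- H %*% p$Wn + M %*% p$Wnei + rowRep(p$b, nrow(H))
  G <- act$f(Z)
  if (normalize) {
    s <- sqrt(rowSums(G^2) + 1e-12)
    out <- G / s
  } else {
    s <- NULL
    out <- G
  }
  list(out = out, cache = list(H = H, M = M, Z = Z, G = G, s = s))
}

gcnBwd <- function(dY, p, cache, Anorm, act) {
  G <- cache$G
  if (!is.null(cache$s)) {
    s <- cache$s
    dG <- dY / s - G * (rowSums(dY * G) / s^3)
  } else {
    dG <- dY
  }
  dZ <- dG * act$d(cache$Z, G)
  g <- list(Wn = crossprod(cache$H, dZ),
            Wnei = crossprod(cache$M, dZ),
            b = colSums(dZ))
  dH <- tcrossprod(dZ, p$Wn) + crossprod(Anorm, tcrossprod(dZ, p$Wnei))
  list(grads = g, dX = dH)
}

# ---- combination of the pre-GCN skip path with the GCN output

initCombiner <- function(d, type) {
  if (type == "concat")
    list(Wc = glorot(2 * d, d), bc = rep(0, d))
  else  # conv_recurrent: shared input map U, recurrent map V
    list(U = glorot(d, d), V = glorot(d, d), bc = rep(0, d))
}

combFwd <- function(skip, g, p, act, type) {
  if (type == "concat") {
    C <- cbind(skip, g)
    d <- denseFwd(C, p$Wc, p$bc)
    out <- act$f(d$out)
    list(out = out, cache = list(type = type, C = C, d = d, z = d$out,
                                 a = out))
  } else {
    # two-step recurrent cell over the sequence [skip, gcn output]
    z1 <- skip %*% p$U + rowRep(p$bc, nrow(skip))
    h1 <- act$f(z1)
    z2 <- g %*% p$U + h1 %*% p$V + rowRep(p$bc, nrow(g))
    h2 <- act$f(z2)
    list(out = h2, cache = list(type = type, skip = skip, g = g,
                                z1 = z1, h1 = h1, z2 = z2, h2 = h2))
  }
}

combBwd <- function(dY, p, cache, act) {
  if (cache$type == "concat") {
    dZ <- dY * act$d(cache$z, cache$a)
    bg <- denseBwd(dZ, cache$d, p$Wc)
    d <- ncol(bg$dX) / 2
    list(grads = list(Wc = bg$dW, bc = bg$db),
         dSkip = bg$dX[, 1:d, drop = FALSE],
         dG = bg$dX[, (d + 1):(2 * d), drop = FALSE])
  } else {
    dZ2 <- dY * act$d(cache$z2, cache$h2)
    gU <- crossprod(cache$g, dZ2)
    gV <- crossprod(cache$h1, dZ2)
    gb <- colSums(dZ2)
    dG <- tcrossprod(dZ2, p$U)
    dH1 <- tcrossprod(dZ2, p$V)
    dZ1 <- dH1 * act$d(cache$z1, cache$h1)
    gU <- gU + crossprod(cache$skip, dZ1)
    gb <- gb + colSums(dZ1)
    dSkip <- tcrossprod(dZ1, p$U)
    list(grads = list(U = gU, V = gV, bc = gb), dSkip = dSkip, dG = dG)
  }
}

softmaxRows <- function(L) {
  e <- exp(L - apply(L, 1, max))
  e / rowSums(e)
}

# ---- parameter-tree helpers and optimizers

mapTree <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1]]
  if (is.list(a)) {
    # align subtrees by name where available (member order may differ)
    keys <- if (!is.null(names(a)) && all(nzchar(names(a))))
      names(a) else seq_along(a)
    out <- lapply(keys, function(k)
      do.call(mapTree, c(list(f), lapply(trees, `[[`, k))))
    names(out) <- if (is.character(keys)) keys else names(a)
    out
  } else {
    do.call(f, trees)
  }
}

zerosLike <- function(tree) mapTree(function(p) p * 0, tree)

makeOptimizer <- function(name, lr, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8) {
  env <- new.env()
  env$t <- 0L
  env$step <- function(params, grads) {
    env$t <- env$t + 1L
    t <- env$t
    if (is.null(env$m)) {
      env$m <- zerosLike(params)
      env$v <- zerosLike(params)
    }
    if (name == "SGD") {
      return(mapTree(function(p, g) p - lr * g, params, grads))
    }
    env$m <- mapTree(function(m, g) beta1 * m + (1 - beta1) * g,
                     env$m, grads)
    if (name == "Adamax") {
      env$v <- mapTree(function(v, g) pmax(beta2 * v, abs(g)),
                       env$v, grads)
      return(mapTree(function(p, m, v)
        p - lr / (1 - beta1^t) * m / (v + eps), params, env$m, env$v))
    }
    env$v <- mapTree(function(v, g) beta2 * v + (1 - beta2) * g^2,
                     env$v, grads)
    bias1 <- 1 - beta1^t
    bias2 <- 1 - beta2^t
    if (name == "Adam") {
      mapTree(function(p, m, g, v)
        p - lr * (m / bias1) / (sqrt(v / bias2) + eps),
        params, env$m, grads, env$v)
    } else {  # Nadam: Nesterov lookahead on the first moment
      mapTree(function(p, m, g, v)
        p - lr * (beta1 * m / bias1 + (1 - beta1) * g / bias1) /
          (sqrt(v / bias2) + eps),
        params, env$m, grads, env$v)
    }
  }
  env
}

#' One graph-convolution message-passing step
#'
#' h'_u = sigma(Wn h_u + Wnei agg_{v in N(u)} h_v + b), optionally
#' followed by row-wise L2 normalization of the embeddings. With sum
#' aggregation the neighbor term is the plain neighbor sum; with mean
#' aggregation it is divided by the node degree (isolated nodes
#' contribute zero).
#'
#' @param H n x d matrix of node embeddings
#' @param A n x n symmetric binary adjacency with zero diagonal
#' @param Wn,Wnei d x d' weight matrices for self and neighbor terms
#' @param b bias vector of length d'
#' @param activation "ELU", "ReLU", "Tanh" or "identity"
#' @param aggregate "sum" or "mean"
#' @param normalize L2-normalize each updated embedding
#' @return n x d' matrix of updated embeddings
#' @export
messagePass <- function(H, A, Wn, Wnei, b = rep(0, ncol(Wn)),
                        activation = "identity",
                        aggregate = c("sum", "mean"), normalize = FALSE) {
  aggregate <- match.arg(aggregate)
  if (!isSymmetric(unname(as.matrix(A))) || any(diag(as.matrix(A)) != 0))
    stopf("adjacency error: A must be symmetric with zero diagonal")
  act <- actFun(activation)
  Anorm <- normalizeAdjacency(A, aggregate)
  gcnFwd(H, Anorm, list(Wn = Wn, Wnei = Wnei, b = b), act,
         normalize = normalize)$out
}

normalizeAdjacency <- function(A, aggregate) {
  A <- as.matrix(A) * 1.0
  if (aggregate == "mean") {
    deg <- rowSums(A)
    A / ifelse(deg > 0, deg, 1)
  } else A
}

#' Forward pass of one feed-forward block
#'
#' Batch normalization, dropout, two dense layers with the configured
#' activation, and an additive skip connection around the whole block
#' (a linear projection when the input width differs from the output
#' width). In training mode batch statistics are used and running
#' statistics updated; in inference mode the stored running statistics
#' are used and dropout is off.
#'
#' @param X n x d input matrix
#' @param params block parameters from \code{\link{initFfnBlockParams}}
#' @param buffers batch-norm running statistics (list with mean, var)
#' @param activation "ELU", "ReLU" or "Tanh"
#' @param dropout dropout rate in [0, 1)
#' @param training logical mode switch
#' @param momentum running-statistics momentum (0 makes running stats
#'   equal the last batch statistics)
#' @return list with `out` (n x hidden[2]) and updated `buffers`
#' @export
ffnBlock <- function(X, params, buffers = NULL, activation = "ELU",
                     dropout = 0.2, training = FALSE, momentum = 0.9) {
  if (!is.matrix(X)) stopf("dimension error: X must be a matrix")
  if (ncol(X) != length(params$gamma))
    stopf("dimension error: X has %d columns, block expects %d",
          ncol(X), length(params$gamma))
  if (is.null(buffers)) buffers <- emptyBnBuf(ncol(X))
  r <- ffnBlockFwd(X, params, buffers, actFun(activation), dropout,
                   training, momentum)
  list(out = r$out, buffers = r$buf)
}

#' Initialize feed-forward block parameters
#'
#' @param nIn input width
#' @param hidden integer pair of dense-layer widths
#' @param seed RNG seed
#' @return named list of parameter matrices
#' @export
initFfnBlockParams <- function(nIn, hidden = c(64L, 64L), seed = 1L) {
  withSeed(seed, initFfnBlock(nIn, hidden))
}
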