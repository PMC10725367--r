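#' Default hyperparameter search space
#'
#' Bounds of the quantitative hyperparameters: hidden units 32-64,
#' learning rate 0.001-0.01, batch size 64-128, dropout rate 0.3-0.7.
#'
#' @return named list of list(lower, upper, integer)
#' @export
tuningSpace <- function() {
  list(hiddenUnits = list(lower = 32, upper = 64, integer = TRUE),
       learningRate = list(lower = 0.001, upper = 0.01, integer = FALSE),
       batchSize = list(lower = 64, upper = 128, integer = TRUE),
       dropout = list(lower = 0.3, upper = 0.7, integer = FALSE))
}

rbfKernel <- function(A, B, ell = 0.3) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * ell^2))
}

# GP posterior mean/sd at candidate points (unit cube coordinates)
gpPosterior <- function(X, y, Xc, ell = 0.3, noise = 1e-4) {
  mu <- mean(y); sc <- stats::sd(y)
  if (!is.finite(sc) || sc == 0) sc <- 1
  ys <- (y - mu) / sc
  K <- rbfKernel(X, X, ell) + diag(noise + 1e-8, nrow(X))
  Ks <- rbfKernel(Xc, X, ell)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  m <- as.numeric(Ks %*% alpha)
  v <- 1 - rowSums((Ks %*% chol2inv(L)) * Ks)
  list(mean = m * sc + mu, sd = sqrt(pmax(v, 0)) * sc)
}

#' Bayesian hyperparameter optimization with a GP surrogate and UCB
#'
#' Maximizes a black-box objective over a bounded box. Initial design
#' points come from a Latin hypercube; subsequent points maximize the
#' upper confidence bound mean + kappa * sd of a Gaussian-process
#' surrogate over random candidates. Integer dimensions are rounded
#' after acquisition. Returns the argmax of the observed objective and
#' the full trial log.
#'
#' @param objective function taking a named list of values, returning a
#'   scalar to maximize (e.g. validation accuracy)
#' @param space named list of list(lower, upper, integer); see
#'   \code{\link{tuningSpace}}
#' @param budget total number of objective evaluations
#' @param nInit initial Latin-hypercube evaluations (default
#'   min(2 + 2d, budget))
#' @param kappa UCB exploration coefficient
#' @param seed RNG seed
#' @return list with `best` (named list), `bestValue`, `trials`
#'   (data.frame of all evaluated points and values)
#' @export
tuneBayesian <- function(objective, space = tuningSpace(), budget = 25L,
                         nInit = NULL, kappa = 2, seed = 1L) {
  d <- length(space)
  if (d == 0L) stopf("parameter error: empty search space")
  lower <- vapply(space, function(s) s$lower, numeric(1))
  upper <- vapply(space, function(s) s$upper, numeric(1))
  isInt <- vapply(space, function(s) isTRUE(s$integer), logical(1))
  if (any(upper < lower))
    stopf("parameter error: upper bound below lower bound")
  span <- upper - lower
  toUnit <- function(x) if (all(span == 0)) x * 0 else
    (x - lower) / ifelse(span > 0, span, 1)
  fromUnit <- function(u) {
    x <- lower + u * span
    x[isInt] <- round(x[isInt])
    x
  }
  evalPoint <- function(x) {
    objective(stats::setNames(as.list(x), names(space)))
  }
  if (all(span == 0)) {  # one-point space
    x <- fromUnit(rep(0, d))
    val <- evalPoint(x)
    trials <- data.frame(as.list(stats::setNames(x, names(space))),
                         value = val)
    return(list(best = as.list(stats::setNames(x, names(space))),
                bestValue = val, trials = trials))
  }
  if (is.null(nInit)) nInit <- min(2L + 2L * d, budget)
  if (budget < nInit)
    stopf("parameter error: budget must cover the initial design (%d)",
          nInit)
  withSeed(seed, {
    U <- lhs::randomLHS(nInit, d)
    X <- matrix(NA_real_, 0, d)
    y <- numeric(0)
    for (i in seq_len(nInit)) {
      x <- fromUnit(U[i, ])
      y <- c(y, evalPoint(x))
      X <- rbind(X, toUnit(x))
    }
    while (length(y) < budget) {
      cand <- matrix(stats::runif(256 * d), 256, d)
      post <- gpPosterior(X, y, cand)
      ucb <- post$mean + kappa * post$sd
      x <- fromUnit(cand[which.max(ucb), ])
      y <- c(y, evalPoint(x))
      X <- rbind(X, toUnit(x))
    }
    pts <- matrix(t(apply(X, 1, fromUnit)), nrow = nrow(X), ncol = d)
    colnames(pts) <- names(space)
    trials <- data.frame(pts, value = y)
    best <- which.max(y)
    list(best = as.list(trials[best, names(space), drop = FALSE]),
         bestValue = y[best], trials = trials)
  })
}
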