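#' Welch's two-sample t-test for one feature
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. Sign convention: benign minus
#' malignant (the first group minus the second). Zero-variance groups
#' are handled by the same formula: identical constant groups give
#' t = 0, p = 1; constant groups with different means give an infinite
#' statistic and p = 0.
#'
#' @param x,y numeric vectors (n >= 2 each, finite)
#' @return list with statistic `t`, `p`, and degrees of freedom `df`
#' @export
welchTTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stopf("insufficient-data error: each group needs n >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("insufficient-data error: non-finite values")
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mx == my) return(list(t = 0, p = 1, df = nx + ny - 2))
    return(list(t = sign(mx - my) * Inf, p = 0, df = nx + ny - 2))
  }
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, df = df)
}

#' Per-feature significance testing of a feature table
#'
#' Runs Welch's t-test (benign minus malignant) on each of the ten
#' features. No multiple-testing correction is applied by default,
#' matching per-feature reporting; `adjust = "bonferroni"` is available.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param alpha significance level (default 0.05)
#' @param adjust "none" or "bonferroni"
#' @return data.frame with feature, t_value, p_value, significant
#' @export
featureTTest <- function(table, alpha = 0.05,
                         adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  X <- nodeFeatures(table)
  lab <- nodeLabels(table)
  res <- lapply(featureNames(), function(f) {
    r <- welchTTest(X[lab == "benign", f], X[lab == "malignant", f])
    data.frame(feature = f, t_value = r$t, p_value = r$p)
  })
  out <- do.call(rbind, res)
  if (adjust == "bonferroni")
    out$p_value <- stats::p.adjust(out$p_value, method = "bonferroni")
  out$significant <- out$p_value < alpha
  out
}

#' Gaussian kernel density estimate on an explicit grid
#'
#' Average of Gaussian kernels of width `bandwidth` centered at the
#' observations, evaluated at the grid points. Default bandwidth is
#' Silverman's rule (stats::bw.nrd0).
#'
#' @param values numeric sample (n >= 2)
#' @param grid evaluation points
#' @param bandwidth kernel standard deviation (> 0)
#' @return numeric vector of non-negative densities on the grid
#' @export
densityEstimate <- function(values, grid, bandwidth = NULL) {
  if (length(values) < 2L)
    stopf("insufficient-data error: need n >= 2 values")
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(values)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stopf("parameter error: bandwidth must be > 0")
  n <- length(values)
  vapply(grid, function(g)
    sum(stats::dnorm((g - values) / bandwidth)) / (n * bandwidth),
    numeric(1))
}

#' Per-class density plots for each feature
#'
#' Writes one PNG with a panel per feature showing the benign and
#' malignant density curves.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param path output PNG path
#' @export
plotFeatureDensities <- function(table, path) {
  X <- nodeFeatures(table)
  lab <- nodeLabels(table)
  grDevices::png(path, width = 1400, height = 700)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 5), mar = c(3, 3, 2, 1))
  for (f in featureNames()) {
    vb <- X[lab == "benign", f]
    vm <- X[lab == "malignant", f]
    rg <- range(c(vb, vm))
    pad <- diff(rg) * 0.2 + 1e-9
    grid <- seq(rg[1] - pad, rg[2] + pad, length.out = 200)
    db <- densityEstimate(vb, grid)
    dm <- densityEstimate(vm, grid)
    graphics::plot(grid, db, type = "l", col = "darkorange", lwd = 2,
                   ylim = c(0, max(db, dm)), main = f, xlab = "", ylab = "")
    graphics::lines(grid, dm, col = "steelblue", lwd = 2)
  }
  invisible(path)
}
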