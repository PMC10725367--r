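#' Spearman rank correlation of two feature vectors
#'
#' Pearson correlation of average ranks, equal to the classical
#' S = 1 - 6 sum(d^2) / (n (n^2 - 1)) when there are no ties. A constant
#' vector has all ranks tied and no defined correlation.
#'
#' @param u,v numeric vectors of equal length n >= 2
#' @return score in [-1, 1]
#' @export
spearmanScore <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2L)
    stopf("parameter error: vectors must have equal length n >= 2")
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stopf("parameter error: non-finite values")
  ru <- rank(u); rv <- rank(v)
  du <- ru - mean(ru); dv <- rv - mean(rv)
  su <- sum(du^2); sv <- sum(dv^2)
  if (su == 0 || sv == 0)
    stopf("undefined-correlation error: constant vector (all ranks tied)")
  sum(du * dv) / sqrt(su * sv)
}

#' Build the all-pairs Spearman edge table of a feature table
#'
#' Every unordered pair of rows (images) gets one edge weighted by the
#' Spearman rank correlation of the two 10-feature rows, giving
#' n(n-1)/2 edges, ordered by ascending source then target.
#'
#' @param table a \linkS4class{FeatureTable}, or a plain numeric matrix
#'   of node feature rows
#' @return an \linkS4class{EdgeTable}
#' @export
buildEdgeTable <- function(table) {
  X <- if (is(table, "FeatureTable")) nodeFeatures(table) else table
  n <- nrow(X)
  if (n < 2L) stopf("parameter error: need at least 2 rows")
  R <- t(apply(X, 1, rank))
  Rc <- R - rowMeans(R)
  ss <- rowSums(Rc^2)
  if (any(ss == 0))
    stopf("undefined-correlation error: row %d has all feature ranks tied",
          which(ss == 0)[1])
  Z <- Rc / sqrt(ss)
  C <- tcrossprod(Z)
  C <- pmin(pmax(C, -1), 1)
  iu <- which(upper.tri(C), arr.ind = TRUE)
  ord <- order(iu[, 1], iu[, 2])
  iu <- iu[ord, , drop = FALSE]
  new("EdgeTable",
      edges = data.frame(source = iu[, 1], target = iu[, 2],
                         weight = C[iu]),
      nNodes = as.integer(n))
}

#' Threshold an edge table on the correlation score
#'
#' `tau = NULL` keeps every edge; `tau = 1` keeps only exact-unit
#' correlations (to within 1e-12); otherwise edges with weight >= tau
#' are kept.
#'
#' @param edgeTable an \linkS4class{EdgeTable}
#' @param tau threshold in [-1, 1], or NULL for no threshold
#' @return filtered \linkS4class{EdgeTable}
#' @export
thresholdEdges <- function(edgeTable, tau = NULL) {
  if (is.null(tau)) return(edgeTable)
  if (!is.finite(tau) || tau < -1 || tau > 1)
    stopf("parameter error: tau must be in [-1, 1] or NULL")
  e <- edgeTable@edges
  keep <- if (tau == 1) abs(e$weight - 1) <= 1e-12 else e$weight >= tau
  new("EdgeTable", edges = e[keep, , drop = FALSE],
      nNodes = edgeTable@nNodes)
}

#' Binary adjacency matrix of an edge table
#'
#' Symmetric with zero diagonal; A[i, j] = 1 exactly for listed pairs.
#' Dense for graphs up to 2000 nodes, sparse (Matrix) above, with
#' identical semantics.
#'
#' @param edgeTable an \linkS4class{EdgeTable}
#' @return binary matrix or Matrix::sparseMatrix
#' @export
toAdjacency <- function(edgeTable) {
  n <- edgeTable@nNodes
  e <- edgeTable@edges
  if (nrow(e) > 0 && (min(e$source) < 1L || max(e$target) > n))
    stopf("index error: node id out of range [1, %d]", n)
  if (n <= 2000L) {
    A <- matrix(0L, n, n)
    if (nrow(e) > 0) {
      A[cbind(e$source, e$target)] <- 1L
      A[cbind(e$target, e$source)] <- 1L
    }
    A
  } else {
    Matrix::sparseMatrix(i = c(e$source, e$target),
                         j = c(e$target, e$source),
                         x = 1, dims = c(n, n))
  }
}

#' Assemble a LesionGraph from a feature table
#'
#' Builds the all-pairs Spearman edge table, optionally removes
#' class-anomalous edges (\code{\link{filterAnomalies}}), optionally
#' thresholds, and materializes the adjacency.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param tau correlation threshold or NULL
#' @param filter remove strong cross-class / weak same-class edges first
#' @return a \linkS4class{LesionGraph}; when `filter = TRUE` the
#'   \linkS4class{FilterReport} is attached as attribute "filterReport"
#' @export
buildGraph <- function(table, tau = NULL, filter = FALSE) {
  et <- buildEdgeTable(table)
  report <- NULL
  if (filter) {
    fr <- filterAnomalies(et, nodeLabels(table))
    et <- fr$edgeTable
    report <- fr$report
  }
  et <- thresholdEdges(et, tau)
  g <- new("LesionGraph", X = nodeFeatures(table),
           labels = nodeLabels(table), edgeTable = et,
           adjacency = toAdjacency(et))
  if (!is.null(report)) attr(g, "filterReport") <- report
  g
}

#' Percentage reduction in edge count
#'
#' @param nBefore,nAfter edge counts before and after thresholding
#' @return reduction in percent
#' @export
edgeReductionPct <- function(nBefore, nAfter) {
  100 * (nBefore - nAfter) / nBefore
}

#' Write an edge table as CSV
#'
#' Header Source,Target,Correlation; node ids are 1-based.
#'
#' @param edgeTable an \linkS4class{EdgeTable}
#' @param path output CSV path
#' @export
writeEdgeTable <- function(edgeTable, path) {
  e <- edgeTable@edges
  utils::write.csv(data.frame(Source = e$source, Target = e$target,
                              Correlation = e$weight),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an edge table written by \code{\link{writeEdgeTable}}
#'
#' @param path CSV path
#' @param nNodes node count of the graph the edges refer to
#' @return an \linkS4class{EdgeTable}
#' @export
readEdgeTable <- function(path, nNodes) {
  df <- utils::read.csv(path)
  new("EdgeTable",
      edges = data.frame(source = as.integer(df$Source),
                         target = as.integer(df$Target),
                         weight = df$Correlation),
      nNodes = as.integer(nNodes))
}
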