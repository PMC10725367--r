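#' Cluster edges by correlation strength
#'
#' Partition at the two fixed cut points: weight < `weakCut` is weak,
#' weight >= `strongCut` is strong, everything in between is "other".
#'
#' @param edgeTable an \linkS4class{EdgeTable}
#' @param weakCut weak cut point (exclusive below; default 0.4)
#' @param strongCut strong cut point (inclusive above; default 0.7)
#' @return list of three EdgeTables: weak, strong, other
#' @export
clusterEdges <- function(edgeTable, weakCut = 0.4, strongCut = 0.7) {
  e <- edgeTable@edges
  sub <- function(keep) new("EdgeTable", edges = e[keep, , drop = FALSE],
                            nNodes = edgeTable@nNodes)
  list(weak = sub(e$weight < weakCut),
       strong = sub(e$weight >= strongCut),
       other = sub(e$weight >= weakCut & e$weight < strongCut))
}

#' Construct a FilterReport from removal counts
#'
#' Encodes the two-branch removal arithmetic: the intermediate count is
#' total minus strong cross-class removals, and the final count
#' additionally subtracts weak same-class removals.
#'
#' @param total,strong,strongCrossRemoved,weak,weakSameRemoved counts
#' @return a validated \linkS4class{FilterReport}
#' @export
filterReport <- function(total, strong, strongCrossRemoved, weak,
                         weakSameRemoved) {
  new("FilterReport", counts = c(
    total = total, strong = strong,
    strongCrossRemoved = strongCrossRemoved,
    weak = weak, weakSameRemoved = weakSameRemoved,
    intermediate = total - strongCrossRemoved,
    final = total - strongCrossRemoved - weakSameRemoved))
}

#' Remove class-anomalous edges
#'
#' Two disjoint removal branches: strong edges (weight >= `strongCut`)
#' joining nodes of distinct classes, and weak edges (weight <
#' `weakCut`) joining nodes of the same class. Edges in the middle band
#' always pass through. The operation is idempotent and conserves
#' counts: |output| + removals = |input|.
#'
#' @param edgeTable an \linkS4class{EdgeTable}
#' @param labels character vector of node classes, indexed by node id
#' @param weakCut,strongCut the two cut points (defaults 0.4 / 0.7)
#' @return list with `edgeTable` (filtered) and `report`
#'   (\linkS4class{FilterReport})
#' @export
filterAnomalies <- function(edgeTable, labels, weakCut = 0.4,
                            strongCut = 0.7) {
  e <- edgeTable@edges
  if (nrow(e) > 0 && max(e$target) > length(labels))
    stopf("label error: node %d has no label", max(e$target))
  if (any(is.na(labels)))
    stopf("label error: missing label for node %d", which(is.na(labels))[1])
  same <- labels[e$source] == labels[e$target]
  strong <- e$weight >= strongCut
  weak <- e$weight < weakCut
  dropStrong <- strong & !same
  dropWeak <- weak & same
  keep <- !(dropStrong | dropWeak)
  report <- filterReport(
    total = nrow(e), strong = sum(strong),
    strongCrossRemoved = sum(dropStrong),
    weak = sum(weak), weakSameRemoved = sum(dropWeak))
  list(edgeTable = new("EdgeTable", edges = e[keep, , drop = FALSE],
                       nNodes = edgeTable@nNodes),
       report = report)
}

#' Write a FilterReport as JSON
#'
#' @param report a \linkS4class{FilterReport}
#' @param path output JSON path
#' @export
writeFilterReport <- function(report, path) {
  writeJsonAtomic(as.list(report@counts), path)
}
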