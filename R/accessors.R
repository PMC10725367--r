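#' @rdname accessors
#' @name accessors
#' @title Accessors for SonoGraph objects
#' @description Slot access for the core S4 classes: node features,
#'   labels, ids, edges, node counts, adjacency, confusion counts and
#'   metrics.
#' @param object a SonoGraph S4 object
NULL

setGeneric("nodeFeatures", function(object) standardGeneric("nodeFeatures"))
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))
setGeneric("edgeData", function(object) standardGeneric("edgeData"))
setGeneric("nNodes", function(object) standardGeneric("nNodes"))
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
setGeneric("confusionCounts", function(object) standardGeneric("confusionCounts"))
setGeneric("metricValues", function(object) standardGeneric("metricValues"))
setGeneric("filterCounts", function(object) standardGeneric("filterCounts"))

#' @rdname accessors
#' @export
setMethod("nodeFeatures", "FeatureTable", function(object) object@features)
#' @rdname accessors
#' @export
setMethod("nodeFeatures", "LesionGraph", function(object) object@X)
#' @rdname accessors
#' @export
setMethod("nodeLabels", "FeatureTable", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("nodeLabels", "LesionGraph", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("nodeIds", "FeatureTable", function(object) object@ids)
#' @rdname accessors
#' @export
setMethod("edgeData", "EdgeTable", function(object) object@edges)
#' @rdname accessors
#' @export
setMethod("edgeData", "LesionGraph", function(object) object@edgeTable@edges)
#' @rdname accessors
#' @export
setMethod("nNodes", "EdgeTable", function(object) object@nNodes)
#' @rdname accessors
#' @export
setMethod("nNodes", "LesionGraph", function(object) nrow(object@X))
#' @rdname accessors
#' @export
setMethod("adjacency", "LesionGraph", function(object) object@adjacency)
#' @rdname accessors
#' @export
setMethod("confusionCounts", "EvalReport", function(object) object@confusion)
#' @rdname accessors
#' @export
setMethod("metricValues", "EvalReport", function(object) object@metrics)
#' @rdname accessors
#' @export
setMethod("filterCounts", "FilterReport", function(object) object@counts)

#' Numeric class codes of a feature table
#'
#' Benign maps to 0, malignant to 1.
#'
#' @param object a FeatureTable or LesionGraph
#' @return integer vector of 0/1 codes
#' @export
labelCodes <- function(object) {
  as.integer(nodeLabels(object) == "malignant")
}

#' Convert a FeatureTable to the n x 12 node table
#'
#' Columns: id, the ten features, label (0 = benign, 1 = malignant).
#'
#' @param x a FeatureTable
#' @param row.names,optional,... passed through for generic compatibility
#' @return data.frame with 12 columns
#' @export
as.data.frame.FeatureTable <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(id = x@ids, as.data.frame(x@features),
             label = labelCodes(x), row.names = row.names)
}

setMethod("as.data.frame", "FeatureTable", as.data.frame.FeatureTable)
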