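#' @include AllClasses.R
NULL

#' Node identifiers of a network
#'
#' @param x A \linkS4class{MotifNetwork}.
#' @return Character vector of node identifiers.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edge matrix of a network
#'
#' @param x A \linkS4class{MotifNetwork}.
#' @return Two-column character matrix; within each row the endpoints are in
#'   lexicographic order.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Canonical edge keys of a network
#'
#' Each undirected edge is keyed by its two endpoints in lexicographic order,
#' separated by a single space.  These keys identify edges throughout the
#' package: an embedding is a sorted character vector of such keys.
#'
#' @param x A \linkS4class{MotifNetwork}.
#' @return Character vector of edge keys.
#' @export
setGeneric("edgeKeys", function(x) standardGeneric("edgeKeys"))

#' Node degrees
#'
#' @param x A \linkS4class{MotifNetwork}.
#' @return Named integer vector of degrees.
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' Number of nodes / edges
#'
#' @param x A \linkS4class{MotifNetwork}.
#' @return Integer count.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname numNodes
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Embeddings stored in an equivalence class
#'
#' @param x An \linkS4class{EquivalenceClass}.
#' @return For \code{classEmbeddings}, the list of all embeddings (the F1
#'   support); for \code{disjointEmbeddings}, the currently selected mutually
#'   disjoint subset.
#' @export
setGeneric("classEmbeddings", function(x) standardGeneric("classEmbeddings"))

#' @rdname classEmbeddings
#' @export
setGeneric("disjointEmbeddings", function(x) standardGeneric("disjointEmbeddings"))

#' Frequency counts of an equivalence class
#'
#' @param x An \linkS4class{EquivalenceClass}.
#' @return \code{f1Count} returns the number of embeddings (the F1 measure);
#'   \code{disjointCount} returns the size of the disjoint embedding set (the
#'   F2 or F3 measure, depending on how the class was counted).
#' @export
setGeneric("f1Count", function(x) standardGeneric("f1Count"))

#' @rdname f1Count
#' @export
setGeneric("disjointCount", function(x) standardGeneric("disjointCount"))

#' Pattern summary accessors
#'
#' @param x An \linkS4class{EquivalenceClass}.
#' @return \code{patternEdgeCount} / \code{patternNodeCount}: integer size of
#'   the pattern this class represents.
#' @export
setGeneric("patternEdgeCount", function(x) standardGeneric("patternEdgeCount"))

#' @rdname patternEdgeCount
#' @export
setGeneric("patternNodeCount", function(x) standardGeneric("patternNodeCount"))

#' Classes contained in a motif report
#'
#' @param x A \linkS4class{MotifReport}.
#' @return List of \linkS4class{EquivalenceClass} objects, sorted by
#'   decreasing frequency.
#' @export
setGeneric("reportClasses", function(x) standardGeneric("reportClasses"))
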