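# Graph data model, file I/O and preprocessing.

#' Construct a MotifNetwork from an edge table
#'
#' Normalises the input to a simple undirected graph: reversed duplicates of
#' an edge collapse to one, self-loops are dropped with a warning, and
#' repeated edges are collapsed.  Isolated nodes can be carried along via
#' \code{nodes}.
#'
#' @param edges Two-column character matrix or data frame of endpoints, or a
#'   character vector of edge keys (\code{"u v"}).
#' @param nodes Optional character vector of node identifiers to include even
#'   if they touch no edge (e.g. nodes whose only edge was a self-loop).
#' @return A \linkS4class{MotifNetwork}.
#' @examples
#' g <- MotifNetwork(cbind(c("a", "b"), c("b", "c")))
#' numEdges(g)
#' @export
MotifNetwork <- function(edges, nodes = character(0)) {
  if (is.character(edges) && is.null(dim(edges)))
    edges <- splitEdgeKeys(edges)
  edges <- as.matrix(edges)
  if (nrow(edges) > 0) {
    mode(edges) <- "character"
    u <- pmin(edges[, 1], edges[, 2])
    v <- pmax(edges[, 1], edges[, 2])
    loops <- u == v
    if (any(loops)) {
      warning(sprintf("dropped %d self-loop(s)", sum(loops)))
      nodes <- c(nodes, u[loops])
      u <- u[!loops]; v <- v[!loops]
    }
    keys <- paste(u, v)
    dup <- duplicated(keys)
    u <- u[!dup]; v <- v[!dup]
    ord <- order(paste(u, v))
    u <- u[ord]; v <- v[ord]
  } else {
    u <- v <- character(0)
  }
  allNodes <- sort(unique(c(u, v, nodes)))
  adj <- lapply(stats::setNames(vector("list", length(allNodes)), allNodes),
                function(x) character(0))
  for (i in seq_along(u)) {
    adj[[u[i]]] <- c(adj[[u[i]]], v[i])
    adj[[v[i]]] <- c(adj[[v[i]]], u[i])
  }
  adj <- lapply(adj, sort)
  methods::new("MotifNetwork", nodes = allNodes,
               edgeMat = cbind(u, v, deparse.level = 0), adj = adj)
}

#' @describeIn networkNodes Node identifiers of a MotifNetwork.
#' @export
setMethod("networkNodes", "MotifNetwork", function(x) x@nodes)

#' @describeIn networkEdges Edge matrix of a MotifNetwork.
#' @export
setMethod("networkEdges", "MotifNetwork", function(x) x@edgeMat)

#' @describeIn edgeKeys Canonical edge keys of a MotifNetwork.
#' @export
setMethod("edgeKeys", "MotifNetwork", function(x) {
  if (nrow(x@edgeMat) == 0) return(character(0))
  paste(x@edgeMat[, 1], x@edgeMat[, 2])
})

#' @describeIn nodeDegrees Degrees of a MotifNetwork.
#' @export
setMethod("nodeDegrees", "MotifNetwork",
          function(x) lengths(x@adj))

#' @describeIn numNodes Node count.
#' @export
setMethod("numNodes", "MotifNetwork", function(x) length(x@nodes))

#' @describeIn numNodes Edge count.
#' @export
setMethod("numEdges", "MotifNetwork", function(x) nrow(x@edgeMat))

#' Neighbours of a node
#'
#' @param g A \linkS4class{MotifNetwork}.
#' @param v A node identifier.
#' @return Sorted character vector of neighbours.
#' @export
neighborsOf <- function(g, v) {
  if (!v %in% g@nodes) stop("unknown node: ", v)
  g@adj[[v]]
}

#' Read an undirected network from a whitespace-delimited edge list
#'
#' Each non-comment line names one edge by its two endpoint identifiers;
#' additional tokens on a line are ignored.  Lines starting with \code{'#'}
#' and blank lines are skipped.  Duplicate edges (including reversed
#' duplicates) collapse to a single edge, and self-loops are dropped with a
#' warning while their node is kept.
#'
#' @param path Path to the edge-list file.
#' @return A \linkS4class{MotifNetwork}.
#' @examples
#' tf <- tempfile()
#' writeLines(c("# toy", "a b", "b a", "b c"), tf)
#' readEdgeList(tf)
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- lengths(toks) < 2
  if (any(bad))
    stop(sprintf("malformed edge-list line %d: '%s' (need two tokens)",
                 idx[which(bad)[1]], lines[idx[which(bad)[1]]]))
  if (length(toks) == 0) stop("empty graph: no edges in ", path)
  em <- t(vapply(toks, function(t) t[1:2], character(2)))
  MotifNetwork(em)
}

#' Write a network as a whitespace-delimited edge list
#'
#' Inverse of \code{\link{readEdgeList}}: a round-trip preserves the node and
#' edge sets exactly (isolated nodes are recorded as comment lines).
#'
#' @param g A \linkS4class{MotifNetwork}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeEdgeList <- function(g, path) {
  em <- networkEdges(g)
  iso <- setdiff(networkNodes(g), unique(as.vector(em)))
  lines <- character(0)
  if (length(iso))
    lines <- paste("# isolated:", iso)
  lines <- c(lines, paste(em[, 1], em[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write GraphML (interoperability)
#'
#' Thin wrappers over \pkg{igraph}'s GraphML support; node identifiers are
#' taken from / stored in the \code{name} vertex attribute.
#'
#' @param path File path.
#' @return \code{readGraphML} returns a \linkS4class{MotifNetwork}.
#' @export
readGraphML <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  em <- igraph::as_edgelist(ig, names = TRUE)
  mode(em) <- "character"
  MotifNetwork(em, nodes = as.character(igraph::V(ig)$name))
}

#' @rdname readGraphML
#' @param g A \linkS4class{MotifNetwork}.
#' @export
writeGraphML <- function(g, path) {
  igraph::write_graph(asIgraph(g), path, format = "graphml")
  invisible(path)
}

# convert to igraph (used for components, GraphML, and as a cross-check
# oracle in the test suite)
asIgraph <- function(g) {
  ig <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ig <- igraph::add_vertices(ig, length(g@nodes), name = g@nodes)
  if (nrow(g@edgeMat) > 0)
    ig <- igraph::add_edges(ig, t(matrix(match(g@edgeMat, g@nodes),
                                         ncol = 2)))
  ig
}

#' Drop connected components smaller than the motif size
#'
#' Nodes in components with fewer than \code{mu} nodes can never take part in
#' a motif of \code{mu} nodes, so they are removed before discovery.
#'
#' @param g A \linkS4class{MotifNetwork}.
#' @param mu Minimum component size (number of nodes) to keep; positive
#'   integer.
#' @return A \linkS4class{MotifNetwork} restricted to the surviving
#'   components.  Idempotent.
#' @examples
#' g <- MotifNetwork(cbind(c("a", "b", "x"), c("b", "c", "y")))
#' numNodes(pruneSmallComponents(g, 3))
#' @export
pruneSmallComponents <- function(g, mu) {
  stopifnot(mu >= 1)
  if (numNodes(g) == 0) return(g)
  comp <- igraph::components(asIgraph(g))
  keepNodes <- g@nodes[comp$csize[comp$membership] >= mu]
  em <- g@edgeMat
  keepEdge <- em[, 1] %in% keepNodes & em[, 2] %in% keepNodes
  MotifNetwork(em[keepEdge, , drop = FALSE], nodes = keepNodes)
}

#' Is an edge set connected?
#'
#' @param edges Character vector of edge keys (\code{"u v"}), non-empty.
#' @return \code{TRUE} iff the subgraph spanned by the edges is connected.
#' @examples
#' isConnectedEdgeSet(c("a b", "b c"))
#' isConnectedEdgeSet(c("a b", "c d"))
#' @export
isConnectedEdgeSet <- function(edges) {
  if (length(edges) == 0) stop("empty edge set")
  em <- splitEdgeKeys(edges)
  nodes <- unique(as.vector(em))
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (i in seq_len(nrow(em))) {
    adj[[em[i, 1]]] <- c(adj[[em[i, 1]]], em[i, 2])
    adj[[em[i, 2]]] <- c(adj[[em[i, 2]]], em[i, 1])
  }
  seen <- stats::setNames(logical(length(nodes)), nodes)
  queue <- nodes[1]
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    fresh <- adj[[v]][!seen[adj[[v]]]]
    seen[fresh] <- TRUE
    queue <- c(queue, fresh)
  }
  all(seen)
}

# subgraph degrees / adjacency of a bare edge set, used by the pattern code
edgeSetAdjacency <- function(edges) {
  em <- splitEdgeKeys(edges)
  nodes <- sort(unique(as.vector(em)))
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (i in seq_len(nrow(em))) {
    adj[[em[i, 1]]] <- c(adj[[em[i, 1]]], em[i, 2])
    adj[[em[i, 2]]] <- c(adj[[em[i, 2]]], em[i, 1])
  }
  lapply(adj, sort)
}
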