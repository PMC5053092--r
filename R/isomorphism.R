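# Canonical-label filters and the exact isomorphism test.  Patterns are bare
# edge sets (non-induced semantics): two edge sets are isomorphic iff an
# edge-preserving node bijection exists between the graphs they span; extra
# adjacencies in the host graph are irrelevant.

#' Degree vector of a pattern
#'
#' First canonical label: the sorted multiset of node degrees within the
#' subgraph spanned by the edge set.  Isomorphic patterns have identical
#' degree vectors; the converse does not hold, so the vector is a filter, not
#' a certificate.
#'
#' @param edges Character vector of edge keys of a connected pattern.
#' @return Sorted integer vector.
#' @examples
#' degreeVector(c("a b", "a c", "b c"))   # triangle: 2 2 2
#' degreeVector(c("a b", "b c"))          # 2-edge path: 1 1 2
#' @export
degreeVector <- function(edges) {
  if (length(edges) == 0) stop("empty edge set")
  if (!isConnectedEdgeSet(edges)) stop("disconnected edge set")
  adj <- edgeSetAdjacency(edges)
  sort(as.integer(lengths(adj)))
}

#' Distance/degree node labels of a pattern
#'
#' Second canonical label.  With \eqn{x} the diameter of the pattern,
#' \eqn{x_{ij}} the shortest-path distance between nodes \eqn{i} and \eqn{j}
#' within the pattern, and \eqn{d(v_j)} the pattern degree of node \eqn{j},
#' node \eqn{i} receives the label \deqn{\sum_{j \in V} 2^{x - x_{ij} - d(v_j)},}
#' where the sum runs over all pattern nodes including \eqn{j = i} (with
#' \eqn{x_{ii} = 0}).  The sorted label vector is invariant under node
#' relabelling; it is compared with an absolute tolerance of 1e-9.
#'
#' @param edges Character vector of edge keys of a connected pattern.
#' @return Sorted numeric vector, one label per node.
#' @examples
#' nodesVector(c("a b", "a c", "b c"))   # triangle: 1 1 1
#' @export
nodesVector <- function(edges) {
  if (length(edges) == 0) stop("empty edge set")
  adj <- edgeSetAdjacency(edges)
  nodes <- names(adj)
  n <- length(nodes)
  deg <- lengths(adj)
  # BFS all-pairs distances (patterns are tiny)
  dist <- matrix(NA_integer_, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    d <- stats::setNames(rep(NA_integer_, n), nodes)
    d[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      fresh <- adj[[v]][is.na(d[adj[[v]]])]
      d[fresh] <- d[v] + 1L
      queue <- c(queue, fresh)
    }
    dist[s, ] <- d
  }
  if (anyNA(dist)) stop("disconnected edge set")
  x <- max(dist)
  labels <- vapply(seq_len(n), function(i)
    sum(2^(x - dist[i, ] - deg)), numeric(1))
  sort(labels)
}

#' Exact isomorphism test between two patterns
#'
#' Backtracking search for an edge-preserving bijection between the node sets
#' of two bare edge sets.  Candidates are paired by equal degree, assignments
#' are ordered by descending degree, and each extension is checked against
#' all previously mapped nodes (adjacency must agree in both directions), so
#' incompatible branches are pruned early.  Patterns are small (a few dozen
#' edges at most), so this is fast in practice.
#'
#' @param e1,e2 Character vectors of edge keys of connected patterns.
#' @return \code{TRUE} iff the patterns are isomorphic.
#' @examples
#' areIsomorphic(c("a b", "b c"), c("x y", "y z"))
#' areIsomorphic(c("a b", "b c"), c("x y", "x z", "y z"))
#' @export
areIsomorphic <- function(e1, e2) {
  if (length(e1) != length(e2)) return(FALSE)
  a1 <- edgeSetAdjacency(e1)
  a2 <- edgeSetAdjacency(e2)
  if (length(a1) != length(a2)) return(FALSE)
  d1 <- lengths(a1); d2 <- lengths(a2)
  if (!identical(sort(as.integer(d1)), sort(as.integer(d2)))) return(FALSE)
  n1 <- names(a1)[order(-d1, names(a1))]
  n2 <- names(a2)
  mapping <- stats::setNames(rep(NA_character_, length(n1)), n1)
  used <- stats::setNames(logical(length(n2)), n2)
  extend <- function(k) {
    if (k > length(n1)) return(TRUE)
    u <- n1[k]
    for (w in n2[!used & d2[n2] == d1[u]]) {
      ok <- TRUE
      for (prev in n1[seq_len(k - 1)]) {
        adj1 <- prev %in% a1[[u]]
        adj2 <- mapping[[prev]] %in% a2[[w]]
        if (adj1 != adj2) { ok <- FALSE; break }
      }
      if (ok) {
        mapping[[u]] <<- w; used[[w]] <<- TRUE
        if (extend(k + 1)) return(TRUE)
        mapping[[u]] <<- NA_character_; used[[w]] <<- FALSE
      }
    }
    FALSE
  }
  extend(1)
}

#' Assign a candidate pattern to an equivalence class
#'
#' Filter cascade used during discovery: candidate classes must first match
#' the candidate's degree vector exactly, then its nodes vector within
#' tolerance; only the survivors receive the exact isomorphism test.
#'
#' @param edges Character vector of edge keys of a connected candidate.
#' @param classes List of \linkS4class{EquivalenceClass} objects, pairwise
#'   non-isomorphic.
#' @param tol Absolute tolerance for nodes-vector comparison.
#' @return Index of the matching class, or \code{NA_integer_} when the
#'   pattern is new.  More than one isomorphic class is an internal error.
#' @export
classifyPattern <- function(edges, classes, tol = 1e-9) {
  if (length(classes) == 0) return(NA_integer_)
  dv <- degreeVector(edges)
  nv <- NULL
  hits <- integer(0)
  for (i in seq_along(classes)) {
    cl <- classes[[i]]
    if (!identical(cl@degreeVector, dv)) next
    if (is.null(nv)) nv <- nodesVector(edges)
    if (length(cl@nodesVector) != length(nv) ||
        any(abs(cl@nodesVector - nv) > tol)) next
    if (areIsomorphic(edges, cl@representative)) hits <- c(hits, i)
  }
  if (length(hits) > 1)
    stop("internal invariant violation: classes are not pairwise non-isomorphic")
  if (length(hits) == 1) hits else NA_integer_
}

#' Create an equivalence class from its first embedding
#'
#' @param edges Sorted character vector of edge keys of the first embedding.
#' @param basicId \code{"M1"}..\code{"M4"} for basic building patterns, else
#'   \code{""}.
#' @return An \linkS4class{EquivalenceClass} with cached canonical labels and
#'   a single embedding.
#' @export
newEquivalenceClass <- function(edges, basicId = "") {
  edges <- sort(edges)
  methods::new("EquivalenceClass", representative = edges,
               degreeVector = degreeVector(edges),
               nodesVector = nodesVector(edges),
               embeddings = list(edges), disjointEmb = list(),
               measure = "", basicId = basicId)
}

#' @describeIn classEmbeddings All embeddings (F1 support).
#' @export
setMethod("classEmbeddings", "EquivalenceClass", function(x) x@embeddings)

#' @describeIn classEmbeddings Disjoint embeddings under the active measure.
#' @export
setMethod("disjointEmbeddings", "EquivalenceClass", function(x) x@disjointEmb)

#' @describeIn f1Count F1 count of a class.
#' @export
setMethod("f1Count", "EquivalenceClass", function(x) length(x@embeddings))

#' @describeIn f1Count Disjoint (F2/F3) count of a class.
#' @export
setMethod("disjointCount", "EquivalenceClass",
          function(x) length(x@disjointEmb))

#' @describeIn patternEdgeCount Edge count of the pattern.
#' @export
setMethod("patternEdgeCount", "EquivalenceClass",
          function(x) length(x@representative))

#' @describeIn patternEdgeCount Node count of the pattern.
#' @export
setMethod("patternNodeCount", "EquivalenceClass",
          function(x) length(embeddingNodes(x@representative)))
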