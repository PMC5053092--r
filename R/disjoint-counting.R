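# Disjoint frequency: extract a maximal set of mutually disjoint embeddings
# per pattern.  Two heuristics: the explicit overlap-graph / min-degree
# greedy (for derived patterns, whose embedding lists are short), and the
# algebraic variant (mandatory for the four basic patterns, whose embedding
# lists are large) which never materialises overlap-graph adjacency.

#' Build the overlap graph of a pattern's embeddings
#'
#' @param embeddings List of embeddings (sorted character vectors of edge
#'   keys), pairwise distinct.
#' @param measure \code{"F2"}: two embeddings are adjacent when they share at
#'   least one edge; \code{"F3"}: when they share at least one node.
#' @return An \linkS4class{OverlapGraph}.
#' @examples
#' og <- buildOverlapGraph(list(c("a b", "b c"), c("b c", "c d")), "F2")
#' og@degrees
#' @export
buildOverlapGraph <- function(embeddings, measure = c("F2", "F3")) {
  measure <- match.arg(measure)
  n <- length(embeddings)
  if (n == 0)
    return(methods::new("OverlapGraph", adjacency = list(),
                        degrees = integer(0), measure = measure))
  items <- if (measure == "F2") embeddings
           else lapply(embeddings, embeddingNodes)
  univ <- unique(unlist(items))
  M <- Matrix::sparseMatrix(i = rep(seq_len(n), lengths(items)),
                            j = match(unlist(items), univ), x = 1,
                            dims = c(n, length(univ)))
  P <- Matrix::tcrossprod(M)
  # symmetric sparse storage keeps one triangle only; expand before reading
  P <- methods::as(methods::as(P, "generalMatrix"), "TsparseMatrix")
  keep <- P@i != P@j
  ii <- P@i[keep] + 1L; jj <- P@j[keep] + 1L
  adjacency <- unname(split(jj, factor(ii, levels = seq_len(n))))
  adjacency <- lapply(adjacency, function(v) sort(as.integer(v)))
  methods::new("OverlapGraph", adjacency = adjacency,
               degrees = lengths(adjacency, use.names = FALSE),
               measure = measure)
}

#' Greedy maximal independent set on an overlap graph
#'
#' Iterated minimum-degree selection: pick the alive node with the smallest
#' current degree, add it to the independent set, delete it and its
#' neighbours, update the remaining degrees, repeat until the graph is empty.
#' Ties are broken by the embeddings' canonical keys (or by index when no
#' keys are supplied), making the result deterministic.
#'
#' @param og An \linkS4class{OverlapGraph}.
#' @param keys Optional character vector of embedding keys for tie-breaking.
#' @return Sorted integer vector of selected embedding indices; always an
#'   independent and maximal set.
#' @export
greedyMIS <- function(og, keys = NULL) {
  n <- length(og@adjacency)
  if (n == 0) return(integer(0))
  if (is.null(keys)) keys <- sprintf("%09d", seq_len(n))
  alive <- rep(TRUE, n)
  degs <- og@degrees
  chosen <- integer(0)
  ordKey <- order(keys)
  rankKey <- integer(n); rankKey[ordKey] <- seq_len(n)
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[order(degs[cand], rankKey[cand])][1]
    chosen <- c(chosen, best)
    removed <- c(best, og@adjacency[[best]][alive[og@adjacency[[best]]]])
    alive[removed] <- FALSE
    for (r in removed)
      for (nb in og@adjacency[[r]])
        if (alive[nb]) degs[nb] <- degs[nb] - 1L
  }
  sort(chosen)
}

#' Greedy disjoint-set extraction via algebraic overlap counts
#'
#' The scalable variant used for the basic building patterns: each
#' embedding's overlap count is computed algebraically
#' (\code{\link{algebraicOverlapCount}}), embeddings are sorted by ascending
#' count (ties by canonical key), and a single pass accepts every embedding
#' that shares no edge (F2) or node (F3) with the ones accepted before it,
#' tracked by a used-edge/used-node set.  Overlap-graph adjacency is never
#' materialised.  The output is verified to be an independent, maximal set in
#' the test suite.
#'
#' @param g A \linkS4class{MotifNetwork}.
#' @param embeddings Full enumeration of \code{pid}'s embeddings in \code{g}.
#' @param pid One of \code{basicPatternIds()}.
#' @param measure \code{"F2"} or \code{"F3"}.
#' @return Sorted integer vector of selected embedding indices.
#' @export
greedyMISAlgebraic <- function(g, embeddings, pid, measure = c("F2", "F3")) {
  measure <- match.arg(measure)
  n <- length(embeddings)
  if (n == 0) return(integer(0))
  counts <- vapply(embeddings, function(e)
    algebraicOverlapCount(g, e, pid, measure), numeric(1))
  keys <- vapply(embeddings, embeddingKey, character(1))
  ord <- order(counts, keys)
  used <- new.env(hash = TRUE)
  chosen <- integer(0)
  for (i in ord) {
    items <- if (measure == "F2") embeddings[[i]]
             else embeddingNodes(embeddings[[i]])
    free <- TRUE
    for (it in items) if (!is.null(used[[it]])) { free <- FALSE; break }
    if (free) {
      chosen <- c(chosen, i)
      for (it in items) used[[it]] <- TRUE
    }
  }
  sort(chosen)
}

#' Count the disjoint frequency of an equivalence class
#'
#' Fills the class's disjoint embedding set and returns the updated class.
#' Basic building patterns use the algebraic single-pass heuristic
#' (\code{\link{greedyMISAlgebraic}}); derived patterns use the explicit
#' overlap graph and \code{\link{greedyMIS}}.  The resulting count is the
#' class's F2 (edge-disjoint) or F3 (node-disjoint) frequency; retrieve it
#' with \code{disjointCount()}.
#'
#' @param g A \linkS4class{MotifNetwork}.
#' @param ec An \linkS4class{EquivalenceClass} with populated embeddings.
#' @param measure \code{"F2"} or \code{"F3"}.
#' @return The updated \linkS4class{EquivalenceClass}.
#' @examples
#' g <- fig1Graph()
#' cls <- newEquivalenceClass(c("a b", "a c", "b c"))
#' cls@embeddings <- enumerateBasic(g, "M2")
#' disjointCount(countFrequency(g, cls, "F2"))
#' @export
countFrequency <- function(g, ec, measure = c("F2", "F3")) {
  measure <- match.arg(measure)
  embs <- ec@embeddings
  idx <- if (nzchar(ec@basicId)) {
    greedyMISAlgebraic(g, embs, ec@basicId, measure)
  } else {
    og <- buildOverlapGraph(embs, measure)
    greedyMIS(og, keys = vapply(embs, embeddingKey, character(1)))
  }
  ec@disjointEmb <- embs[idx]
  ec@measure <- measure
  ec
}
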