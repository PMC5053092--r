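# The top-level discovery algorithm: seed with the four basic building
# patterns, then iteratively join current motif instances with basic-pattern
# instances, classify the products into equivalence classes, recount disjoint
# frequencies, prune below-threshold classes, and harvest classes that reach
# the target size.

#' Discovery configuration
#'
#' @param mu Target motif size: number of nodes (\code{sizeMode = "nodes"},
#'   the default, \code{mu >= 3}) or number of edges (\code{sizeMode =
#'   "edges"}, \code{mu >= 2}).
#' @param sizeMode \code{"nodes"} or \code{"edges"}.
#' @param alpha Minimum disjoint frequency, a positive integer.
#' @param measure \code{"F2"} (edge-disjoint) or \code{"F3"} (node-disjoint).
#' @param joinSource Which basic-pattern instance set feeds the joins:
#'   \code{"disjoint"} (the mutually disjoint sets, the default) or
#'   \code{"all"} (every enumerated instance; higher recall, higher cost).
#' @param seed Integer seed recorded in the configuration (discovery itself
#'   is deterministic; the seed feeds downstream randomised steps).
#' @return A named list of validated settings.
#' @export
discoveryConfig <- function(mu, sizeMode = c("nodes", "edges"), alpha = 1,
                            measure = c("F2", "F3"),
                            joinSource = c("disjoint", "all"), seed = 1L) {
  sizeMode <- match.arg(sizeMode)
  measure <- match.arg(measure)
  joinSource <- match.arg(joinSource)
  if (alpha < 1) stop("alpha must be >= 1")
  minMu <- if (sizeMode == "nodes") 3 else 2
  if (mu < minMu)
    stop(sprintf("mu must be >= %d when sizeMode = '%s'", minMu, sizeMode))
  list(mu = as.integer(mu), sizeMode = sizeMode, alpha = as.integer(alpha),
       measure = measure, joinSource = joinSource, seed = as.integer(seed))
}

#' Join a motif instance with a basic-pattern instance
#'
#' Two embeddings join when they share at least one edge and their union is
#' strictly larger than the motif instance; the union is then connected by
#' construction.
#'
#' @param m,b Embeddings (sorted character vectors of edge keys) in the same
#'   graph.
#' @return The union embedding, or \code{NULL} when the pair does not join.
#' @examples
#' joinPair(c("a b", "a c", "b c"), c("b c", "b e"))
#' @export
joinPair <- function(m, b) {
  if (!any(b %in% m)) return(NULL)
  u <- sort(unique(c(m, b)))
  if (length(u) == length(m)) return(NULL)
  u
}

classSize <- function(ec, sizeMode) {
  if (sizeMode == "edges") patternEdgeCount(ec) else patternNodeCount(ec)
}
embSize <- function(emb, sizeMode) {
  if (sizeMode == "edges") length(emb)
  else length(embeddingNodes(emb))
}

#' One join iteration of the discovery algorithm
#'
#' Attempts to join every motif instance in the current classes' disjoint
#' sets with every basic-pattern instance (from the configured join source)
#' sharing an edge with it.  Each product is classified by the filter cascade
#' (\code{\link{classifyPattern}}): a product of a known pattern is appended
#' to that class unless an identical embedding is already stored; an unseen
#' pattern opens a new class.  All touched classes are then recounted
#' (\code{\link{countFrequency}}) and classes below the frequency threshold
#' are deleted.
#'
#' @param g A \linkS4class{MotifNetwork}.
#' @param current List of \linkS4class{EquivalenceClass} objects with
#'   populated disjoint sets.
#' @param basics List of basic-pattern \linkS4class{EquivalenceClass}
#'   objects.
#' @param cfg A \code{\link{discoveryConfig}}.
#' @return List of surviving new-generation classes (frequency >=
#'   \code{alpha}), each recounted.
#' @export
runIteration <- function(g, current, basics, cfg) {
  # index basic instances by the edges they contain
  binst <- list()
  for (bc in basics) {
    src <- if (cfg$joinSource == "disjoint") bc@disjointEmb else bc@embeddings
    binst <- c(binst, src)
  }
  edgeIndex <- new.env(hash = TRUE)
  for (i in seq_along(binst))
    for (e in binst[[i]]) edgeIndex[[e]] <- c(edgeIndex[[e]], i)

  newClasses <- list()
  newKeys <- list()    # per new class: environment of embedding keys
  sizeCap <- cfg$mu
  for (cc in current) {
    for (m in cc@disjointEmb) {
      cand <- unique(unlist(lapply(m, function(e) edgeIndex[[e]])))
      for (bi in cand) {
        prod <- joinPair(m, binst[[bi]])
        if (is.null(prod)) next
        if (embSize(prod, cfg$sizeMode) > sizeCap) next
        idx <- classifyPattern(prod, newClasses)
        if (is.na(idx)) {
          nc <- newEquivalenceClass(prod)
          newClasses[[length(newClasses) + 1L]] <- nc
          ke <- new.env(hash = TRUE)
          ke[[embeddingKey(prod)]] <- TRUE
          newKeys[[length(newKeys) + 1L]] <- ke
        } else {
          k <- embeddingKey(prod)
          if (is.null(newKeys[[idx]][[k]])) {
            newKeys[[idx]][[k]] <- TRUE
            newClasses[[idx]]@embeddings <-
              c(newClasses[[idx]]@embeddings, list(prod))
          }
        }
      }
    }
  }
  newClasses <- lapply(newClasses, function(ec)
    countFrequency(g, ec, cfg$measure))
  Filter(function(ec) disjointCount(ec) >= cfg$alpha, newClasses)
}

#' Discover frequent disjoint motifs
#'
#' Runs the full discovery: prune components smaller than the motif can
#' reach, enumerate and count the four basic building patterns, drop basics
#' below the frequency threshold, then iterate \code{\link{runIteration}},
#' harvesting every class whose pattern reaches the target size with
#' disjoint frequency at least \code{alpha}.  The run terminates when an
#' iteration produces no surviving class below the target size (or after a
#' safety cap of \code{mu} iterations; each join adds one or two edges).
#' Classes exceeding the target size are discarded as they arise.
#'
#' The join strategy guarantees that every reported pattern exists in the
#' graph, but not that every instance of it is found; the report is sound,
#' not complete.
#'
#' @param g A \linkS4class{MotifNetwork}.
#' @param cfg A \code{\link{discoveryConfig}}.
#' @return A \linkS4class{MotifReport}; classes sorted by decreasing
#'   frequency, ties by canonical pattern key.
#' @examples
#' rep <- findMotifs(fig1Graph(), discoveryConfig(4, "edges", alpha = 2))
#' as(rep, "data.frame")
#' @export
findMotifs <- function(g, cfg) {
  pruneMu <- if (cfg$sizeMode == "nodes") cfg$mu else 3L
  g <- pruneSmallComponents(g, pruneMu)
  if (numEdges(g) == 0)
    return(methods::new("MotifReport", classes = list(), config = cfg))

  basics <- list()
  for (pid in basicPatternIds()) {
    embs <- enumerateBasic(g, pid)
    if (length(embs) == 0) next
    ec <- newEquivalenceClass(embs[[1]], basicId = pid)
    ec@embeddings <- embs
    basics[[length(basics) + 1L]] <- countFrequency(g, ec, cfg$measure)
  }
  basics <- Filter(function(ec) disjointCount(ec) >= cfg$alpha, basics)

  harvested <- list()
  working <- list()
  for (ec in basics) {
    sz <- classSize(ec, cfg$sizeMode)
    if (sz == cfg$mu) harvested[[length(harvested) + 1L]] <- ec
    else if (sz < cfg$mu) working[[length(working) + 1L]] <- ec
  }

  iter <- 0L
  while (length(working) > 0 && iter < cfg$mu) {
    iter <- iter + 1L
    newGen <- runIteration(g, working, basics, cfg)
    working <- list()
    for (ec in newGen) {
      sz <- classSize(ec, cfg$sizeMode)
      if (sz == cfg$mu) harvested[[length(harvested) + 1L]] <- ec
      else if (sz < cfg$mu) working[[length(working) + 1L]] <- ec
    }
  }

  # the same pattern can be harvested in different iterations (joins add one
  # or two edges); merge isomorphic harvests and recount
  merged <- list()
  for (ec in harvested) {
    idx <- classifyPattern(ec@representative, merged)
    if (is.na(idx)) {
      merged[[length(merged) + 1L]] <- ec
    } else {
      seen <- vapply(merged[[idx]]@embeddings, embeddingKey, character(1))
      for (emb in ec@embeddings) {
        k <- embeddingKey(emb)
        if (!k %in% seen) {
          merged[[idx]]@embeddings <-
            c(merged[[idx]]@embeddings, list(emb))
          seen <- c(seen, k)
        }
      }
      merged[[idx]] <- countFrequency(g, merged[[idx]], cfg$measure)
    }
  }
  merged <- Filter(function(ec) disjointCount(ec) >= cfg$alpha, merged)

  freqs <- vapply(merged, disjointCount, integer(1))
  keys <- vapply(merged, function(ec) embeddingKey(ec@representative),
                 character(1))
  merged <- merged[order(-freqs, keys)]
  report <- methods::new("MotifReport", classes = merged, config = cfg)
  validateMotifReport(g, report)
  report
}

#' @describeIn reportClasses Classes of a MotifReport.
#' @export
setMethod("reportClasses", "MotifReport", function(x) x@classes)

setAs("MotifReport", "data.frame", function(from) {
  cls <- from@classes
  data.frame(
    pattern = vapply(cls, function(ec)
      paste(ec@representative, collapse = ";"), character(1)),
    nodes = vapply(cls, patternNodeCount, integer(1)),
    edges = vapply(cls, patternEdgeCount, integer(1)),
    f1 = vapply(cls, f1Count, integer(1)),
    frequency = vapply(cls, disjointCount, integer(1)),
    stringsAsFactors = FALSE)
})

#' Verify the soundness invariants of a motif report
#'
#' Asserts, for every reported class: each disjoint embedding's edges are
#' host edges forming a connected subgraph isomorphic to the class pattern;
#' the disjoint embeddings are pairwise disjoint under the configured
#' measure; each pattern meets the target size and frequency threshold; and
#' the frequency respects the packing bound (frequency x pattern edges <=
#' |E| under F2, frequency x pattern nodes <= |V| under F3).  Called on every
#' \code{\link{findMotifs}} report.
#'
#' @param g The host \linkS4class{MotifNetwork}.
#' @param report A \linkS4class{MotifReport}.
#' @return Invisibly \code{TRUE}; stops on any violation.
#' @export
validateMotifReport <- function(g, report) {
  cfg <- report@config
  hostEdges <- edgeKeys(g)
  for (ec in report@classes) {
    if (classSize(ec, cfg$sizeMode) != cfg$mu)
      stop("reported pattern does not meet the target size")
    if (disjointCount(ec) < cfg$alpha)
      stop("reported pattern below the frequency threshold")
    items <- character(0)
    for (emb in ec@disjointEmb) {
      if (!all(emb %in% hostEdges))
        stop("reported embedding uses edges absent from the host graph")
      if (!isConnectedEdgeSet(emb))
        stop("reported embedding is not connected")
      if (!areIsomorphic(emb, ec@representative))
        stop("reported embedding is not isomorphic to its pattern")
      new <- if (cfg$measure == "F2") emb else embeddingNodes(emb)
      if (any(new %in% items))
        stop("reported embeddings are not pairwise disjoint")
      items <- c(items, new)
    }
    if (cfg$measure == "F2" &&
        disjointCount(ec) * patternEdgeCount(ec) > numEdges(g))
      stop("frequency inflation: edge packing bound violated")
    if (cfg$measure == "F3" &&
        disjointCount(ec) * patternNodeCount(ec) > numNodes(g))
      stop("frequency inflation: node packing bound violated")
  }
  invisible(TRUE)
}

#' Write a motif report to JSON and/or TSV
#'
#' JSON carries the full report (configuration, patterns, and the disjoint
#' embeddings as lists of host edges); the TSV is a per-pattern summary
#' (pattern id, nodes, edges, F1, frequency).
#'
#' @param report A \linkS4class{MotifReport}.
#' @param jsonPath,tsvPath Output paths; \code{NULL} skips that format.
#' @return Invisibly, a character vector of the files written.
#' @export
writeMotifReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  written <- character(0)
  if (!is.null(jsonPath)) {
    payload <- list(
      config = report@config,
      patterns = lapply(report@classes, function(ec) list(
        pattern = ec@representative,
        nodes = patternNodeCount(ec),
        edges = patternEdgeCount(ec),
        f1 = f1Count(ec),
        frequency = disjointCount(ec),
        embeddings = ec@disjointEmb)))
    jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA)
    written <- c(written, jsonPath)
  }
  if (!is.null(tsvPath)) {
    df <- methods::as(report, "data.frame")
    df <- cbind(patternId = seq_len(nrow(df)), df)
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tsvPath)
  }
  invisible(written)
}
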