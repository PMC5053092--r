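# Central S4 containers.  A network is stored as a plain adjacency list keyed
# by opaque node identifiers (protein IDs etc.); no integer re-indexing is
# exposed.  Embeddings are sorted character vectors of canonical edge keys
# ("u v" with u < v lexicographically), so identical subgraphs have identical
# keys and duplicate detection is exact.

#' An undirected simple network
#'
#' The target network in which motifs are searched.  Self-loops and parallel
#' edges are normalised away at construction time.  Node identifiers are
#' opaque strings (any whitespace-free token, e.g. Uniprot accessions).
#'
#' @slot nodes Character vector of node identifiers (sorted).
#' @slot edgeMat Two-column character matrix of edges; within a row the
#'   endpoints are in lexicographic order, rows are sorted by edge key.
#' @slot adj Named list mapping each node to the sorted character vector of
#'   its neighbours.
#'
#' @seealso \code{\link{MotifNetwork}} (constructor),
#'   \code{\link{readEdgeList}}, \code{\link{fig1Graph}}
#' @export
setClass("MotifNetwork",
  representation(nodes = "character", edgeMat = "matrix", adj = "list"))

setValidity("MotifNetwork", function(object) {
  msgs <- character(0)
  em <- object@edgeMat
  if (ncol(em) != 2 && nrow(em) > 0)
    msgs <- c(msgs, "edge matrix must have two columns")
  if (nrow(em) > 0) {
    if (any(em[, 1] >= em[, 2]))
      msgs <- c(msgs, "edges must be canonically ordered and loop-free")
    if (anyDuplicated(paste(em[, 1], em[, 2])))
      msgs <- c(msgs, "parallel edges are not allowed")
  }
  if (!setequal(names(object@adj), object@nodes))
    msgs <- c(msgs, "adjacency names must equal the node set")
  if (sum(lengths(object@adj)) != 2L * nrow(em))
    msgs <- c(msgs, "sum of degrees must be twice the edge count")
  if (length(msgs)) msgs else TRUE
})

#' A pattern equivalence class
#'
#' All embeddings of one motif topology (pattern) in the target network,
#' together with cached canonical labels used for isomorphism filtering and
#' the currently selected set of mutually disjoint embeddings.
#'
#' @slot representative Sorted character vector of edge keys of one embedding;
#'   it plays the role of the pattern (every stored embedding is isomorphic
#'   to it).
#' @slot degreeVector Sorted integer degrees of the pattern's nodes (first
#'   canonical label).
#' @slot nodesVector Sorted real-valued node labels built from pattern
#'   distances and degrees (second canonical label).
#' @slot embeddings List of embeddings; its length is the F1 count.
#' @slot disjointEmb List of pairwise-disjoint embeddings under the measure
#'   in \code{measure}; its length is the F2 (edge-disjoint) or F3
#'   (node-disjoint) count.
#' @slot measure \code{"F2"}, \code{"F3"}, or \code{""} if not yet counted.
#' @slot basicId \code{"M1"}..\code{"M4"} for the four basic building
#'   patterns, otherwise \code{""}.
#'
#' @seealso \code{\link{newEquivalenceClass}}, \code{\link{countFrequency}}
#' @export
setClass("EquivalenceClass",
  representation(representative = "character", degreeVector = "integer",
                 nodesVector = "numeric", embeddings = "list",
                 disjointEmb = "list", measure = "character",
                 basicId = "character"))

setValidity("EquivalenceClass", function(object) {
  msgs <- character(0)
  if (length(object@representative) < 1)
    msgs <- c(msgs, "representative must have at least one edge")
  if (length(object@disjointEmb) > length(object@embeddings))
    msgs <- c(msgs, "disjoint count cannot exceed the F1 count")
  if (length(msgs)) msgs else TRUE
})

#' A motif discovery report
#'
#' Frequent patterns found by \code{\link{findMotifs}}: every reported class
#' meets the requested motif size and its disjoint frequency is at least the
#' configured threshold.
#'
#' @slot classes List of \linkS4class{EquivalenceClass} objects sorted by
#'   decreasing frequency, ties broken by canonical pattern key.
#' @slot config The \code{\link{discoveryConfig}} list used for the run.
#'
#' @seealso \code{\link{findMotifs}}, \code{\link{writeMotifReport}}
#' @export
setClass("MotifReport",
  representation(classes = "list", config = "list"))

#' A motif-abundance z-score report
#'
#' @slot mode \code{"within"} (most abundant motif against all motifs of the
#'   same size in the same graph) or \code{"random"} (against the most
#'   abundant motif in a degree-preserving shuffled ensemble).
#' @slot topFrequency Frequency of the most abundant motif in the target
#'   graph.
#' @slot meanFrequency,sdFrequency Mean and sample standard deviation of the
#'   reference frequencies.
#' @slot z The z-score \code{(topFrequency - meanFrequency) / sdFrequency};
#'   \code{NA} when undefined.
#' @slot defined \code{FALSE} when the reference standard deviation is zero.
#' @slot significant \code{TRUE} when \code{|z| > 2}.
#' @slot frequencies The reference frequencies the score was computed from.
#'
#' @seealso \code{\link{zscoreWithinGraph}}, \code{\link{zscoreVsRandom}}
#' @export
setClass("ZScoreReport",
  representation(mode = "character", topFrequency = "numeric",
                 meanFrequency = "numeric", sdFrequency = "numeric",
                 z = "numeric", defined = "logical", significant = "logical",
                 frequencies = "numeric"))

#' An embedding overlap graph
#'
#' One node per embedding of a pattern; two nodes are adjacent when the
#' embeddings overlap (share an edge under F2, share a node under F3).  The
#' independent sets of this graph are exactly the disjoint embedding sets.
#'
#' @slot adjacency List of integer vectors: \code{adjacency[[i]]} holds the
#'   indices of embeddings overlapping embedding \code{i}.
#' @slot degrees Integer overlap counts, \code{lengths(adjacency)}.
#' @slot measure \code{"F2"} or \code{"F3"}.
#'
#' @seealso \code{\link{buildOverlapGraph}}, \code{\link{greedyMIS}}
#' @export
setClass("OverlapGraph",
  representation(adjacency = "list", degrees = "integer",
                 measure = "character"))

setValidity("OverlapGraph", function(object) {
  msgs <- character(0)
  n <- length(object@adjacency)
  if (!identical(object@degrees, lengths(object@adjacency, use.names = FALSE)))
    msgs <- c(msgs, "degrees must equal adjacency list lengths")
  for (i in seq_len(n)) {
    nb <- object@adjacency[[i]]
    if (any(nb == i)) { msgs <- c(msgs, "self-adjacency not allowed"); break }
    if (any(nb < 1 | nb > n)) { msgs <- c(msgs, "index out of range"); break }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MotifNetwork", function(object) {
  cat(sprintf("MotifNetwork with %d nodes and %d edges\n",
              length(object@nodes), nrow(object@edgeMat)))
  d <- lengths(object@adj)
  if (length(d))
    cat(sprintf("  degree: min %d, median %s, max %d\n",
                min(d), format(stats::median(d)), max(d)))
})

setMethod("show", "EquivalenceClass", function(object) {
  cat(sprintf("EquivalenceClass: pattern with %d nodes / %d edges%s\n",
              length(unique(unlist(strsplit(object@representative, " ",
                                            fixed = TRUE)))),
              length(object@representative),
              if (nzchar(object@basicId)) paste0(" (", object@basicId, ")")
              else ""))
  cat(sprintf("  F1 = %d; disjoint (%s) = %d\n", length(object@embeddings),
              if (nzchar(object@measure)) object@measure else "uncounted",
              length(object@disjointEmb)))
})

setMethod("show", "MotifReport", function(object) {
  cfg <- object@config
  cat(sprintf("MotifReport: %d frequent pattern(s) [size %d %s, alpha %d, %s]\n",
              length(object@classes), cfg$mu, cfg$sizeMode, cfg$alpha,
              cfg$measure))
  df <- as(object, "data.frame")
  if (nrow(df)) print(utils::head(df, 10))
})

setMethod("show", "ZScoreReport", function(object) {
  cat(sprintf("ZScoreReport (%s): top frequency %g, reference mean %.4g, sd %.4g\n",
              object@mode, object@topFrequency, object@meanFrequency,
              object@sdFrequency))
  if (object@defined)
    cat(sprintf("  z = %.4g (%s)\n", object@z,
                if (object@significant) "significant, |z| > 2"
                else "not significant"))
  else cat("  z undefined: zero variance in the reference frequencies\n")
})

setMethod("show", "OverlapGraph", function(object) {
  cat(sprintf("OverlapGraph (%s): %d embeddings, %d overlap pairs\n",
              object@measure, length(object@degrees),
              sum(object@degrees) / 2))
})
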