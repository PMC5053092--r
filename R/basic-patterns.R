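# The four basic building patterns and the algebraic overlap counts.
#
# M1 = 2-edge path, M2 = triangle, M3 = 3-star, M4 = 3-edge path.  These are
# all connected topologies with two or three undirected edges; every larger
# connected pattern arises by joining a smaller pattern with one of them.
#
# The overlap count of an embedding (its degree in the pattern's overlap
# graph) is computed from host-graph degrees, adjacency indicators and
# common-neighbour counts alone -- no pairwise embedding comparisons.  The M1
# edge-overlap case uses the closed form 2 d(c) + d(a) + d(b) - 6; the other
# pattern/measure combinations use inclusion-exclusion derivations that are
# validated exhaustively against a brute-force oracle in the test suite (see
# the methods vignette for the derivations).

#' The basic building pattern identifiers
#'
#' @return \code{c("M1", "M2", "M3", "M4")}: the 2-edge path, the triangle,
#'   the 3-star and the 3-edge path.  Together these are all connected graph
#'   topologies with two or three edges.
#' @export
basicPatternIds <- function() c("M1", "M2", "M3", "M4")

#' Enumerate all embeddings of a basic building pattern
#'
#' Every distinct embedding is returned exactly once: M1 and M3 are
#' enumerated per centre node (all 2- and 3-subsets of its incident edges),
#' M2 per edge with deduplication by sorted node triple, and M4 from its
#' unique middle edge with distinct endpoint extensions.
#'
#' @param g A \linkS4class{MotifNetwork}.
#' @param pid One of \code{basicPatternIds()}.
#' @return List of embeddings (each a sorted character vector of edge keys).
#' @examples
#' g <- fig1Graph()
#' length(enumerateBasic(g, "M2"))   # the two triangles
#' @export
enumerateBasic <- function(g, pid) {
  pid <- match.arg(pid, basicPatternIds())
  out <- list()
  if (pid %in% c("M1", "M3")) {
    k <- if (pid == "M1") 2L else 3L
    for (v in g@nodes) {
      nb <- g@adj[[v]]
      if (length(nb) < k) next
      cmb <- utils::combn(nb, k)
      for (i in seq_len(ncol(cmb)))
        out[[length(out) + 1L]] <- sort(edgeKey(v, cmb[, i]))
    }
  } else if (pid == "M2") {
    seen <- new.env(hash = TRUE)
    em <- g@edgeMat
    for (i in seq_len(nrow(em))) {
      u <- em[i, 1]; v <- em[i, 2]
      for (w in intersect(g@adj[[u]], g@adj[[v]])) {
        tk <- paste(sort(c(u, v, w)), collapse = " ")
        if (!is.null(seen[[tk]])) next
        seen[[tk]] <- TRUE
        out[[length(out) + 1L]] <-
          sort(c(edgeKey(u, v), edgeKey(u, w), edgeKey(v, w)))
      }
    }
  } else { # M4: anchored at the middle edge
    em <- g@edgeMat
    for (i in seq_len(nrow(em))) {
      u <- em[i, 1]; v <- em[i, 2]
      ws <- setdiff(g@adj[[u]], v)
      xs <- setdiff(g@adj[[v]], u)
      for (w in ws) for (x in xs) {
        if (w == x) next
        out[[length(out) + 1L]] <-
          sort(c(edgeKey(w, u), edgeKey(u, v), edgeKey(v, x)))
      }
    }
  }
  out
}

# identify the role of each node in a basic-pattern embedding
basicRoles <- function(emb, pid) {
  ns <- unlist(strsplit(emb, " ", fixed = TRUE))
  tab <- table(ns)
  if (pid == "M1")
    return(list(centre = names(tab)[tab == 2], leaves = names(tab)[tab == 1]))
  if (pid == "M2") return(list(nodes = names(tab)))
  if (pid == "M3")
    return(list(centre = names(tab)[tab == 3], leaves = names(tab)[tab == 1]))
  mids <- names(tab)[tab == 2]; ends <- names(tab)[tab == 1]
  u <- mids[1]; v <- mids[2]
  w <- x <- NA_character_
  for (z in ends) {
    if (edgeKey(z, u) %in% emb) w <- z
    if (edgeKey(z, v) %in% emb) x <- z
  }
  list(path = c(w, u, v, x)) # w-u-v-x
}

# checks that emb is structurally a pid embedding inside g
checkBasicEmbedding <- function(g, emb, pid) {
  if (!all(emb %in% edgeKeys(g)))
    stop("embedding contains edges absent from the graph")
  expected <- switch(pid, M1 = c(1L, 1L, 2L), M2 = c(2L, 2L, 2L),
                     M3 = c(1L, 1L, 1L, 3L), M4 = c(1L, 1L, 2L, 2L))
  dv <- tryCatch(degreeVector(emb), error = function(e) integer(0))
  if (!identical(dv, expected))
    stop("edge set is not an embedding of ", pid)
  invisible(TRUE)
}

#' Algebraic overlap count of a basic-pattern embedding
#'
#' Number of \emph{other} embeddings of the same basic pattern that overlap
#' the given embedding: share at least one edge under \code{"F2"}, at least
#' one node under \code{"F3"}.  This equals the embedding's degree in the
#' pattern's overlap graph, but is computed directly from host-graph degrees,
#' adjacency and common-neighbour counts, without enumerating or comparing
#' other embeddings.
#'
#' For an M1 embedding \{(a,c), (b,c)\} with middle node c, the edge-overlap
#' count is the closed form \code{2*d(c) + d(a) + d(b) - 6}.
#'
#' @param g A \linkS4class{MotifNetwork}.
#' @param emb An embedding of \code{pid} in \code{g} (sorted edge keys).
#' @param pid One of \code{basicPatternIds()}.
#' @param measure \code{"F2"} (edge overlap) or \code{"F3"} (node overlap).
#' @return Non-negative integer overlap count.
#' @examples
#' g <- fig1Graph()
#' algebraicOverlapCount(g, c("a c", "b c"), "M1", "F2")  # 3
#' @export
algebraicOverlapCount <- function(g, emb, pid, measure = c("F2", "F3")) {
  pid <- match.arg(pid, basicPatternIds())
  measure <- match.arg(measure)
  checkBasicEmbedding(g, emb, pid)
  r <- basicRoles(emb, pid)
  d <- function(v) length(g@adj[[v]])
  A <- function(u, v) isAdjacent(g, u, v)
  CN <- function(u, v) commonNeighbours(g, u, v)

  if (pid == "M1") {
    cc <- r$centre; a <- r$leaves[1]; b <- r$leaves[2]
    if (measure == "F2") return(2 * d(cc) + d(a) + d(b) - 6)
    f1 <- function(v) choose2(d(v)) + sum0(degOf(g, g@adj[[v]]) - 1)
    f2 <- function(u, v) A(u, v) * (d(u) + d(v) - 2) + CN(u, v)
    U <- c(cc, a, b)
    trip <- sum0(vapply(U, function(z) {
      o <- setdiff(U, z); A(z, o[1]) * A(z, o[2]) }, numeric(1)))
    return(f1(cc) + f1(a) + f1(b) -
             (f2(cc, a) + f2(cc, b) + f2(a, b)) + trip - 1)
  }

  if (pid == "M2") {
    ns <- r$nodes
    prs <- utils::combn(ns, 2)
    cns <- vapply(seq_len(ncol(prs)),
                  function(i) CN(prs[1, i], prs[2, i]), numeric(1))
    if (measure == "F2") return(sum(cns) - 3)
    trianglesThrough <- function(v)
      sum0(vapply(g@adj[[v]], function(u) CN(u, v), numeric(1))) / 2
    return(sum0(vapply(ns, trianglesThrough, numeric(1))) - sum(cns) + 1 - 1)
  }

  if (pid == "M3") {
    cc <- r$centre; L <- r$leaves
    if (measure == "F2")
      return(choose3(d(cc)) - choose3(d(cc) - 3) - 1 +
               sum0(choose2(degOf(g, L) - 1)))
    U <- c(cc, L)
    g1 <- function(v) choose3(d(v)) + sum0(choose2(degOf(g, g@adj[[v]]) - 1))
    g2 <- function(u, v) {
      com <- intersect(g@adj[[u]], g@adj[[v]])
      A(u, v) * (choose2(d(u) - 1) + choose2(d(v) - 1)) +
        sum0(pmax(degOf(g, com) - 2, 0))
    }
    g3 <- function(u, v, w) {
      s <- 0
      for (z in c(u, v, w)) {
        o <- setdiff(c(u, v, w), z)
        if (A(z, o[1]) && A(z, o[2])) s <- s + max(d(z) - 2, 0)
      }
      s + length(Reduce(intersect, g@adj[c(u, v, w)]))
    }
    g4 <- sum0(vapply(U, function(z) {
      o <- setdiff(U, z)
      as.numeric(all(vapply(o, function(y) A(z, y) == 1L, logical(1))))
    }, numeric(1)))
    pr <- utils::combn(U, 2); tr <- utils::combn(U, 3)
    return(sum0(vapply(U, g1, numeric(1))) -
             sum0(vapply(seq_len(ncol(pr)),
                         function(i) g2(pr[1, i], pr[2, i]), numeric(1))) +
             sum0(vapply(seq_len(ncol(tr)),
                         function(i) g3(tr[1, i], tr[2, i], tr[3, i]),
                         numeric(1))) - g4 - 1)
  }

  # M4: path w-u-v-x with middle edge (u,v)
  p <- r$path; w <- p[1]; u <- p[2]; v <- p[3]; x <- p[4]
  if (measure == "F2") {
    midCount <- function(p1, q1) (d(p1) - 1) * (d(q1) - 1) - CN(p1, q1)
    endVia <- function(p1, q1) sum0(vapply(setdiff(g@adj[[q1]], p1),
      function(rr) d(rr) - 1 - A(rr, p1), numeric(1)))
    N1 <- function(p1, q1) midCount(p1, q1) + endVia(p1, q1) + endVia(q1, p1)
    N2adj <- function(p1, rr) (d(p1) - 1 - A(p1, rr)) + (d(rr) - 1 - A(p1, rr))
    # shared-edge inclusion-exclusion over the three embedding edges
    s <- N1(w, u) + N1(u, v) + N1(v, x) -
      (N2adj(w, v) + N2adj(u, x) +
         (1 + A(u, x) + A(w, v) + A(w, x))) + 1
    return(s - 1)
  }
  U <- c(w, u, v, x)
  h1 <- function(vv) {
    endC <- 0
    for (q in g@adj[[vv]]) for (rr in setdiff(g@adj[[q]], vv))
      endC <- endC + d(rr) - 1 - A(rr, vv)
    midC <- 0
    nb <- g@adj[[vv]]
    if (length(nb) >= 2)
      for (p1 in nb) for (rr in setdiff(nb, p1))
        midC <- midC + d(rr) - 1 - A(rr, p1)
    endC + midC
  }
  h2 <- function(uu, vv) {
    t12 <- A(uu, vv) * (sum0(vapply(setdiff(g@adj[[vv]], uu),
             function(z) d(z) - 1 - A(z, uu), numeric(1))) +
           sum0(vapply(setdiff(g@adj[[uu]], vv),
             function(z) d(z) - 1 - A(z, vv), numeric(1))) +
           (d(uu) - 1) * (d(vv) - 1) - CN(uu, vv))
    t13 <- CN(uu, vv) * ((d(vv) - 1 - A(uu, vv)) + (d(uu) - 1 - A(uu, vv)))
    t14 <- sum0(vapply(setdiff(g@adj[[uu]], vv),
             function(z) CN(z, vv) - A(uu, vv), numeric(1)))
    t12 + t13 + t14
  }
  h3 <- function(u1, u2, u3) {
    s <- 0
    for (m in c(u1, u2, u3)) {
      o <- setdiff(c(u1, u2, u3), m)
      if (A(m, o[1]) && A(m, o[2]))
        s <- s + (d(o[1]) - 1 - A(o[1], o[2])) + (d(o[2]) - 1 - A(o[2], o[1]))
    }
    for (a1 in c(u1, u2, u3)) {
      o <- setdiff(c(u1, u2, u3), a1)
      for (a3 in o) {
        a4 <- setdiff(o, a3)
        if (A(a3, a4))
          s <- s + length(setdiff(intersect(g@adj[[a1]], g@adj[[a3]]), a4))
      }
    }
    s
  }
  h4 <- function(U) {
    cnt <- 0
    perm <- allPermutations(U)
    for (p1 in perm)
      if (A(p1[1], p1[2]) && A(p1[2], p1[3]) && A(p1[3], p1[4]))
        cnt <- cnt + 1
    cnt / 2
  }
  pr <- utils::combn(U, 2); tr <- utils::combn(U, 3)
  sum0(vapply(U, h1, numeric(1))) -
    sum0(vapply(seq_len(ncol(pr)),
                function(i) h2(pr[1, i], pr[2, i]), numeric(1))) +
    sum0(vapply(seq_len(ncol(tr)),
                function(i) h3(tr[1, i], tr[2, i], tr[3, i]), numeric(1))) -
    h4(U) - 1
}

allPermutations <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in allPermutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  out
}
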