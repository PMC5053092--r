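# Independent oracles used throughout the suite.  They deliberately avoid the
# package's production code paths: overlap degrees via dense indicator
# matrices, isomorphism via exhaustive bijection search, maximum independent
# sets via branch and bound, and subgraph enumeration via breadth-first
# growth.

fig1Edges <- function() {
  c("a b", "a c", "b c", "b e", "d e", "e f", "e g", "f g")
}

# the three embeddings of the 4-edge chordal pattern in the toy graph
fig1cEmbeddings <- function() {
  list(sort(c("a b", "a c", "b c", "b e")),
       sort(c("d e", "e f", "e g", "f g")),
       sort(c("b e", "e f", "e g", "f g")))
}

# brute-force overlap degrees: dense indicator matrix cross-product
oracleOverlapCounts <- function(embs, measure) {
  items <- if (measure == "F2") embs
           else lapply(embs, function(e)
             unique(unlist(strsplit(e, " ", fixed = TRUE))))
  univ <- unique(unlist(items))
  M <- matrix(0, length(items), length(univ))
  for (i in seq_along(items)) M[i, match(items[[i]], univ)] <- 1
  P <- tcrossprod(M)
  as.integer(rowSums(P > 0) - 1L)
}

# adjacency list of an overlap graph, brute force (used for exact MIS)
oracleOverlapAdjacency <- function(embs, measure) {
  items <- if (measure == "F2") embs
           else lapply(embs, function(e)
             unique(unlist(strsplit(e, " ", fixed = TRUE))))
  n <- length(items)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (length(intersect(items[[i]], items[[j]])) > 0) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# exact maximum independent set size by branch and bound (<= ~20 nodes)
exactMISSize <- function(adj) {
  n <- length(adj)
  best <- 0L
  recurse <- function(cand, size) {
    if (size + length(cand) <= best) return()
    if (length(cand) == 0) { best <<- max(best, size); return() }
    v <- cand[which.max(lengths(adj[cand]))]
    # branch 1: include v
    recurse(setdiff(cand, c(v, adj[[v]])), size + 1L)
    # branch 2: exclude v
    recurse(setdiff(cand, v), size)
  }
  recurse(seq_len(n), 0L)
  best
}

# exhaustive isomorphism by trying all bijections (patterns <= 8 nodes)
oracleIsomorphic <- function(e1, e2) {
  n1 <- sort(unique(unlist(strsplit(e1, " ", fixed = TRUE))))
  n2 <- sort(unique(unlist(strsplit(e2, " ", fixed = TRUE))))
  if (length(n1) != length(n2) || length(e1) != length(e2)) return(FALSE)
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (p in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
    out
  }
  es1 <- strsplit(e1, " ", fixed = TRUE)
  for (p in perms(n2)) {
    map <- setNames(p, n1)
    mapped <- sort(vapply(es1, function(uv) {
      a <- map[[uv[1]]]; b <- map[[uv[2]]]
      paste(min(a, b), max(a, b))
    }, character(1)))
    if (identical(mapped, sort(e2))) return(TRUE)
  }
  FALSE
}

# all connected k-edge subgraphs of g, as sorted edge-key vectors
enumerateConnectedEdgeSets <- function(g, k) {
  keys <- edgeKeys(g)
  found <- new.env(hash = TRUE)
  grow <- function(cur) {
    id <- paste(cur, collapse = "|")
    if (!is.null(found[[id]])) return()
    found[[id]] <- cur
    if (length(cur) == k) return()
    nodes <- unique(unlist(strsplit(cur, " ", fixed = TRUE)))
    ext <- keys[!keys %in% cur &
                vapply(strsplit(keys, " ", fixed = TRUE),
                       function(uv) any(uv %in% nodes), logical(1))]
    for (e in ext) grow(sort(c(cur, e)))
  }
  for (e in keys) grow(e)
  all <- as.list(found)
  all[vapply(all, length, integer(1)) == k]
}

# random relabelling of an edge set
relabelEdges <- function(edges, seed) {
  set.seed(seed)
  nodes <- unique(unlist(strsplit(edges, " ", fixed = TRUE)))
  map <- setNames(sample(sprintf("z%03d", seq_along(nodes))), nodes)
  sort(vapply(strsplit(edges, " ", fixed = TRUE), function(uv) {
    a <- map[[uv[1]]]; b <- map[[uv[2]]]
    paste(min(a, b), max(a, b))
  }, character(1)))
}

# a random connected pattern with <= maxEdges edges (grown from a BA graph)
randomConnectedPattern <- function(maxEdges, seed) {
  set.seed(seed)
  g <- barabasiAlbert(sample(6:14, 1), sample(1:2, 1), seed = seed + 1)
  keys <- edgeKeys(g)
  cur <- keys[sample(length(keys), 1)]
  target <- sample(2:maxEdges, 1)
  while (length(cur) < target) {
    nodes <- unique(unlist(strsplit(cur, " ", fixed = TRUE)))
    ext <- keys[!keys %in% cur &
                vapply(strsplit(keys, " ", fixed = TRUE),
                       function(uv) any(uv %in% nodes), logical(1))]
    if (length(ext) == 0) break
    cur <- sort(c(cur, ext[sample(length(ext), 1)]))
  }
  cur
}

# does pattern p1 occur as a (connected, edge-subset) subpattern of p2?
isSubPattern <- function(p1, p2) {
  if (length(p1) > length(p2)) return(FALSE)
  subs <- combn(p2, length(p1), simplify = FALSE)
  for (s in subs) {
    ok <- tryCatch(isConnectedEdgeSet(s), error = function(e) FALSE)
    if (ok && areIsomorphic(p1, s)) return(TRUE)
  }
  FALSE
}

# exact F2/F3 of a pattern: all embeddings by exhaustive enumeration, then
# exact MIS on the brute-force overlap graph.  Instances beyond maxEmb
# embeddings return NA (branch and bound would recurse too deep).
exactDisjointFrequency <- function(g, pattern, measure, maxEmb = 60) {
  cand <- enumerateConnectedEdgeSets(g, length(pattern))
  embs <- Filter(function(e) areIsomorphic(e, pattern), cand)
  if (length(embs) == 0) return(0L)
  if (length(embs) > maxEmb) return(NA_integer_)
  exactMISSize(oracleOverlapAdjacency(embs, measure))
}

splitEdgeKeysForTest <- function(keys) {
  matrix(unlist(strsplit(keys, " ", fixed = TRUE)), ncol = 2, byrow = TRUE)
}
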