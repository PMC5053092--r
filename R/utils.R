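# Internal helpers shared across modules.  Edge keys and embedding keys are
# the backbone of duplicate detection: node identifiers contain no
# whitespace (they come from whitespace-split tokens), so "u v" is unambiguous.

# canonical key of an undirected edge
edgeKey <- function(u, v) paste(pmin(u, v), pmax(u, v))

# split edge keys back into a 2-column endpoint matrix
splitEdgeKeys <- function(keys) {
  parts <- strsplit(keys, " ", fixed = TRUE)
  matrix(unlist(parts), ncol = 2, byrow = TRUE)
}

# all nodes touched by a set of edge keys
embeddingNodes <- function(keys) {
  unique(unlist(strsplit(keys, " ", fixed = TRUE)))
}

# stable identity of an embedding (edge keys sorted, newline-joined)
embeddingKey <- function(keys) paste(sort(keys), collapse = "\n")

# sum that tolerates zero-length input (sum over an empty neighbour set)
sum0 <- function(x) if (length(x) == 0) 0 else sum(unlist(x))

# choose(n, k) clipped at zero for n < k, vectorised
choose2 <- function(n) ifelse(n >= 2, n * (n - 1) / 2, 0)
choose3 <- function(n) ifelse(n >= 3, n * (n - 1) * (n - 2) / 6, 0)

# adjacency indicator in a MotifNetwork
isAdjacent <- function(g, u, v) as.integer(v %in% g@adj[[u]])

# common-neighbour count in a MotifNetwork
commonNeighbours <- function(g, u, v) length(intersect(g@adj[[u]], g@adj[[v]]))

degOf <- function(g, v) lengths(g@adj[v], use.names = FALSE)

# derive a reproducible 32-bit sub-seed from (seed, index)
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}
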