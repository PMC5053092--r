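# Statistical significance of motif abundance: a within-graph z-score over
# all motifs of the same size, and an ensemble z-score against
# degree-preserving edge-shuffled random networks.  |z| > 2 is labelled
# significant (two standard deviations from the mean).

#' Disjoint frequencies of all motifs of one size
#'
#' Runs discovery with the frequency threshold set to 1 so that every motif
#' of the requested size is seen, and returns the disjoint frequency of each.
#'
#' @param g A \linkS4class{MotifNetwork}.
#' @param cfg A \code{\link{discoveryConfig}}; its \code{alpha} is forced
#'   to 1.
#' @return Integer vector of frequencies (possibly empty), sorted decreasing.
#' @export
motifFrequencies <- function(g, cfg) {
  cfg$alpha <- 1L
  rep <- findMotifs(g, cfg)
  sort(vapply(rep@classes, disjointCount, integer(1)), decreasing = TRUE)
}

#' Within-graph z-score of the most abundant motif
#'
#' Given the frequencies \eqn{x_1 \ge x_2 \ge \dots \ge x_m} of all motifs of
#' one size in one graph, reports \eqn{z = (x_1 - \bar{x}) / \sigma} with
#' \eqn{\bar{x}} and \eqn{\sigma} the mean and sample standard deviation of
#' all \eqn{m} frequencies.
#'
#' @param frequencies Vector of at least two positive motif frequencies.
#' @return A \linkS4class{ZScoreReport} (mode \code{"within"}); flagged
#'   undefined when all frequencies are equal.
#' @examples
#' zscoreWithinGraph(c(10, 4, 4, 4))   # z = 1.5
#' @export
zscoreWithinGraph <- function(frequencies) {
  if (length(frequencies) < 2)
    stop("need at least two motif frequencies")
  m <- mean(frequencies)
  s <- stats::sd(frequencies)
  defined <- s > 0
  z <- if (defined) (max(frequencies) - m) / s else NA_real_
  methods::new("ZScoreReport", mode = "within",
               topFrequency = max(frequencies), meanFrequency = m,
               sdFrequency = s, z = z, defined = defined,
               significant = defined && abs(z) > 2,
               frequencies = as.numeric(frequencies))
}

#' Degree-preserving edge shuffling
#'
#' Double-edge-swap randomisation: repeatedly pick two edges
#' \eqn{(v_1, v_2)} and \eqn{(u_1, u_2)}, remove them, and insert
#' \eqn{(v_1, u_2)} and \eqn{(u_1, v_2)}.  Proposals that would create a
#' self-loop or a parallel edge are rejected and retried without being
#' counted; \code{swapFactor * |E|} \emph{successful} swaps are performed
#' (with a bounded total number of proposals), so every node keeps its
#' degree, \code{|E|} is unchanged, and the graph stays simple.
#'
#' @param g A \linkS4class{MotifNetwork} with at least two edges.
#' @param swapFactor Number of successful swaps per edge (paper-style
#'   default 10; 0 returns the input unchanged).
#' @param seed Integer seed; a fixed seed gives an identical output graph.
#' @return A shuffled \linkS4class{MotifNetwork} with the same degree
#'   sequence.
#' @export
degreePreservingShuffle <- function(g, swapFactor = 10, seed = 1L) {
  m <- numEdges(g)
  if (m < 2) stop("need at least two edges to shuffle")
  target <- as.integer(swapFactor * m)
  if (target == 0L) return(g)
  set.seed(as.integer(seed))
  eu <- g@edgeMat[, 1]; ev <- g@edgeMat[, 2]
  inSet <- new.env(hash = TRUE)
  for (i in seq_len(m)) inSet[[paste(eu[i], ev[i])]] <- i
  done <- 0L
  attempts <- 0L
  maxAttempts <- max(100L * m, 10L * target)
  while (done < target && attempts < maxAttempts) {
    attempts <- attempts + 1L
    ij <- sample.int(m, 2)
    i <- ij[1]; j <- ij[2]
    v1 <- eu[i]; v2 <- ev[i]
    if (stats::runif(1) < 0.5) { u1 <- eu[j]; u2 <- ev[j] }
    else { u1 <- ev[j]; u2 <- eu[j] }
    # proposed replacements: (v1,u2) and (u1,v2)
    if (v1 == u2 || u1 == v2) next
    k1 <- edgeKey(v1, u2); k2 <- edgeKey(u1, v2)
    if (k1 == k2) next
    old1 <- paste(eu[i], ev[i]); old2 <- paste(eu[j], ev[j])
    if ((!is.null(inSet[[k1]]) && k1 != old1 && k1 != old2) ||
        (!is.null(inSet[[k2]]) && k2 != old1 && k2 != old2)) next
    if (k1 == old1 || k1 == old2 || k2 == old1 || k2 == old2) next
    rm(list = c(old1, old2), envir = inSet)
    p1 <- splitEdgeKeys(k1); p2 <- splitEdgeKeys(k2)
    eu[i] <- p1[1]; ev[i] <- p1[2]
    eu[j] <- p2[1]; ev[j] <- p2[2]
    inSet[[k1]] <- i; inSet[[k2]] <- j
    done <- done + 1L
  }
  if (done < target)
    warning(sprintf("only %d of %d swaps achieved within the proposal budget",
                    done, target))
  MotifNetwork(cbind(eu, ev), nodes = networkNodes(g))
}

#' Ensemble z-score of the most abundant motif
#'
#' Measures how over- or under-represented the most abundant motif of size
#' \code{mu} is, relative to random networks with the same degree sequence.
#' \code{nRandom} degree-preserving shuffled replicas are generated
#' (\code{swapFactor * |E|} successful swaps each; defaults 100 replicas and
#' factor 10), the top motif frequency \eqn{x_i} is measured in each, and
#' \eqn{z = (x - \bar{x}) / \sigma} is reported, where \eqn{x} is the top
#' frequency in the original graph and \eqn{\bar{x}, \sigma} are the mean
#' and sample standard deviation of the \eqn{x_i}.
#'
#' @param g A \linkS4class{MotifNetwork}.
#' @param cfg A \code{\link{discoveryConfig}} fixing motif size and measure;
#'   \code{alpha} is forced to 1.
#' @param nRandom Number of random replicas (>= 2).
#' @param swapFactor Successful swaps per edge for each replica.
#' @param seed Integer master seed; replica \code{i} uses a sub-seed derived
#'   from \code{(seed, i)}, so replicas are independent and reproducible.
#' @return A \linkS4class{ZScoreReport} (mode \code{"random"}).
#' @export
zscoreVsRandom <- function(g, cfg, nRandom = 100, swapFactor = 10,
                           seed = 1L) {
  if (nRandom < 2) stop("nRandom must be >= 2")
  topOf <- function(gr) {
    f <- motifFrequencies(gr, cfg)
    if (length(f) == 0) 0 else max(f)
  }
  x <- topOf(g)
  xi <- vapply(seq_len(nRandom), function(i) {
    gi <- degreePreservingShuffle(g, swapFactor = swapFactor,
                                  seed = deriveSeed(seed, i))
    topOf(gi)
  }, numeric(1))
  m <- mean(xi)
  s <- stats::sd(xi)
  defined <- s > 0
  z <- if (defined) (x - m) / s else NA_real_
  methods::new("ZScoreReport", mode = "random", topFrequency = x,
               meanFrequency = m, sdFrequency = s, z = z, defined = defined,
               significant = defined && abs(z) > 2,
               frequencies = xi)
}

#' Write a z-score report to JSON or TSV
#'
#' @param report A \linkS4class{ZScoreReport}.
#' @param jsonPath,tsvPath Output paths; \code{NULL} skips that format.
#' @return Invisibly, the files written.
#' @export
writeZScoreReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  written <- character(0)
  rec <- list(mode = report@mode, top_frequency = report@topFrequency,
              mean = report@meanFrequency, sd = report@sdFrequency,
              z = if (report@defined) report@z else NULL,
              defined = report@defined, significant = report@significant)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(rec, jsonPath, auto_unbox = TRUE, digits = NA,
                         null = "null")
    written <- c(written, jsonPath)
  }
  if (!is.null(tsvPath)) {
    df <- data.frame(mode = rec$mode, top_frequency = rec$top_frequency,
                     mean = rec$mean, sd = rec$sd,
                     z = ifelse(report@defined, report@z, NA),
                     significant = rec$significant)
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tsvPath)
  }
  invisible(written)
}
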