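# Motif-abundance significance: within-graph and ensemble z-scores, and the
# degree-preserving shuffle.

test_that("within-graph z-score follows the direct arithmetic", {
  r <- zscoreWithinGraph(c(10, 4, 4, 4))
  expect_equal(r@z, 1.5)            # mean 5.5, sample sd 3
  expect_true(r@defined)
  expect_false(r@significant)

  r0 <- zscoreWithinGraph(c(7, 7, 7))
  expect_false(r0@defined)
  expect_true(is.na(r0@z))

  expect_gt(zscoreWithinGraph(c(9, 2))@z, 0)
  expect_error(zscoreWithinGraph(5), "at least two")
})

test_that("degree-preserving shuffle keeps degrees, size and simplicity", {
  g <- barabasiAlbert(30, 2, seed = 21)
  for (s in 1:5) {
    gs <- degreePreservingShuffle(g, swapFactor = 10, seed = s)
    expect_identical(sort(nodeDegrees(gs)), sort(nodeDegrees(g)))
    expect_equal(numEdges(gs), numEdges(g))
    expect_identical(networkNodes(gs), networkNodes(g))
    expect_true(validObject(gs))    # simple by class validity
  }
  # determinism under a fixed seed
  expect_identical(edgeKeys(degreePreservingShuffle(g, 10, seed = 4)),
                   edgeKeys(degreePreservingShuffle(g, 10, seed = 4)))
  # swapFactor 0 returns the input unchanged
  expect_identical(edgeKeys(degreePreservingShuffle(g, 0, seed = 1)),
                   edgeKeys(g))
  # two disjoint edges: one swap rewires across, all degrees stay 1
  g2 <- MotifNetwork(cbind(c("a", "c"), c("b", "d")))
  gs2 <- suppressWarnings(degreePreservingShuffle(g2, 1, seed = 3))
  expect_equal(sort(unname(nodeDegrees(gs2))), c(1, 1, 1, 1))
  expect_equal(numEdges(gs2), 2)
})

test_that("ensemble z-score defaults and degenerate cases behave", {
  expect_equal(formals(zscoreVsRandom)$nRandom, 100)
  expect_equal(formals(zscoreVsRandom)$swapFactor, 10)
  expect_equal(formals(degreePreservingShuffle)$swapFactor, 10)

  # a lone triangle admits no valid swap: every replica equals the input,
  # the reference frequencies have zero variance, z is flagged undefined
  tri <- MotifNetwork(cbind(c("a", "a", "b"), c("b", "c", "c")))
  r <- suppressWarnings(
    zscoreVsRandom(tri, discoveryConfig(3, "nodes"), nRandom = 3,
                   swapFactor = 2, seed = 1))
  expect_false(r@defined)
  expect_true(is.na(r@z))
  expect_error(zscoreVsRandom(tri, discoveryConfig(3, "nodes"), nRandom = 1),
               "nRandom")
})

test_that("z-scores are invariant under node relabelling", {
  g <- barabasiAlbert(18, 2, seed = 33)
  cfg <- discoveryConfig(4, "nodes")
  f1 <- motifFrequencies(g, cfg)
  # relabel every node and recompute
  relab <- setNames(sprintf("q%02d", seq_len(numNodes(g))), networkNodes(g))
  em <- networkEdges(g)
  g2 <- MotifNetwork(cbind(relab[em[, 1]], relab[em[, 2]]))
  f2 <- motifFrequencies(g2, cfg)
  expect_identical(f1, f2)
  if (length(f1) >= 2)
    expect_equal(zscoreWithinGraph(f1)@z, zscoreWithinGraph(f2)@z)
})

test_that("a clustered graph scores as motif-rich against its null ensemble", {
  # five disjoint triangles plus a sparse connector chain: triangle count in
  # the original exceeds the degree-matched shuffled replicas
  tri <- do.call(rbind, lapply(0:4, function(i) {
    v <- paste0("t", i, c("a", "b", "c"))
    cbind(v, c(v[-1], v[1]))
  }))
  chain <- cbind(paste0("t", 0:3, "a"), paste0("t", 1:4, "a"))
  g <- MotifNetwork(rbind(tri, chain))
  r <- suppressWarnings(
    zscoreVsRandom(g, discoveryConfig(3, "nodes"), nRandom = 6,
                   swapFactor = 5, seed = 7))
  if (r@defined) expect_gt(r@z, 0)
  jf <- withr::local_tempfile(fileext = ".json")
  writeZScoreReport(r, jsonPath = jf)
  expect_true(file.exists(jf))
})
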