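# Overlap graphs, the two greedy MIS heuristics, and disjoint frequency.

test_that("overlap graphs reflect shared edges (F2) and shared nodes (F3)", {
  embs <- fig1cEmbeddings()   # S1, S2, S3 of the 4-edge chordal pattern
  og2 <- buildOverlapGraph(embs, "F2")
  # path-shaped: S1-S3 via (b,e); S2-S3 via the right triangle; S1-S2 disjoint
  expect_equal(og2@adjacency, list(3L, 3L, c(1L, 2L)))
  og3 <- buildOverlapGraph(embs, "F3")
  # triangle-shaped: every pair shares node b or e
  expect_equal(og3@degrees, c(2L, 2L, 2L))
  og1 <- buildOverlapGraph(embs[1], "F2")
  expect_equal(og1@degrees, 0L)
})

test_that("greedy MIS reproduces the worked frequencies", {
  embs <- fig1cEmbeddings()
  keys <- vapply(embs, paste, collapse = "|", character(1))
  expect_equal(greedyMIS(buildOverlapGraph(embs, "F2"), keys), c(1L, 2L))
  expect_length(greedyMIS(buildOverlapGraph(embs, "F3"), keys), 1)
  # an edgeless overlap graph keeps every embedding
  free <- list(c("a b", "a c"), c("d e", "d f"), c("g h", "g i"))
  expect_equal(greedyMIS(buildOverlapGraph(free, "F2")), 1:3)
})

test_that("the algebraic single-pass heuristic packs the basic patterns", {
  g <- fig1Graph()
  m1 <- enumerateBasic(g, "M1")
  sel <- greedyMISAlgebraic(g, m1, "M1", "F2")
  expect_length(sel, 4)   # max edge-disjoint 2-path packing of 8 edges
  used <- unlist(m1[sel])
  expect_false(anyDuplicated(used) > 0)
  m2 <- enumerateBasic(g, "M2")
  expect_length(greedyMISAlgebraic(g, m2, "M2", "F2"), 2)
})

test_that("both heuristics return maximal independent sets bounded by the optimum", {
  for (s in 1:8) {
    g <- barabasiAlbert(sample(8:14, 1), 1, seed = 500 + s)
    for (pid in c("M1", "M4")) for (measure in c("F2", "F3")) {
      embs <- enumerateBasic(g, pid)
      if (length(embs) < 2 || length(embs) > 18) next
      adj <- oracleOverlapAdjacency(embs, measure)
      opt <- exactMISSize(adj)
      for (sel in list(
        greedyMIS(buildOverlapGraph(embs, measure),
                  vapply(embs, paste, collapse = "|", character(1))),
        greedyMISAlgebraic(g, embs, pid, measure))) {
        # independent
        for (i in sel) expect_length(intersect(adj[[i]], sel), 0)
        # maximal: every unselected embedding conflicts with a selected one
        for (j in setdiff(seq_along(embs), sel))
          expect_gt(length(intersect(adj[[j]], sel)), 0)
        expect_lte(length(sel), opt)
      }
    }
  }
})

test_that("countFrequency reproduces the worked example and orders F1 >= F2 >= F3", {
  g <- fig1Graph()
  cls <- newEquivalenceClass(fig1cEmbeddings()[[1]])
  cls@embeddings <- fig1cEmbeddings()
  expect_equal(disjointCount(countFrequency(g, cls, "F2")), 2)
  expect_equal(disjointCount(countFrequency(g, cls, "F3")), 1)

  # the two triangles share neither an edge nor a node
  tri <- newEquivalenceClass(c("a b", "a c", "b c"), basicId = "M2")
  tri@embeddings <- enumerateBasic(g, "M2")
  expect_equal(disjointCount(countFrequency(g, tri, "F2")), 2)
  expect_equal(disjointCount(countFrequency(g, tri, "F3")), 2)

  # the 5-edge pattern around e occurs once
  d5 <- sort(c("b e", "d e", "e f", "e g", "f g"))
  c5 <- newEquivalenceClass(d5)
  expect_equal(disjointCount(countFrequency(g, c5, "F2")), 1)

  for (s in 1:5) {
    gb <- barabasiAlbert(15, 2, seed = 900 + s)
    for (pid in basicPatternIds()) {
      embs <- enumerateBasic(gb, pid)
      if (length(embs) == 0) next
      ec <- newEquivalenceClass(embs[[1]], basicId = pid)
      ec@embeddings <- embs
      f2 <- disjointCount(countFrequency(gb, ec, "F2"))
      f3 <- disjointCount(countFrequency(gb, ec, "F3"))
      expect_lte(f3, f2)
      expect_lte(f2, length(embs))
    }
  }
})
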