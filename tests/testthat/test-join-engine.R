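# Joining, iteration, and the full discovery driver.

test_that("join semantics: shared edge, strict growth", {
  tri <- c("a b", "a c", "b c")
  expect_equal(joinPair(tri, c("b c", "b e")),
               sort(c("a b", "a c", "b c", "b e")))
  expect_null(joinPair(tri, c("d e", "e f")))       # disjoint
  expect_null(joinPair(tri, c("a b", "b c")))       # contained, no growth
})

test_that("configurations are validated", {
  expect_error(discoveryConfig(4, alpha = 0), "alpha")
  expect_error(discoveryConfig(2, "nodes"), "mu")
  expect_error(discoveryConfig(1, "edges"), "mu")
  cfg <- discoveryConfig(4, "edges", alpha = 2, measure = "F3",
                         joinSource = "all", seed = 9)
  expect_equal(cfg$mu, 4L)
  expect_equal(cfg$measure, "F3")
})

test_that("one iteration from the basics finds the chordal toy pattern", {
  g <- fig1Graph()
  cfg <- discoveryConfig(4, "edges", alpha = 1)
  basics <- lapply(basicPatternIds(), function(pid) {
    embs <- enumerateBasic(g, pid)
    ec <- newEquivalenceClass(embs[[1]], basicId = pid)
    ec@embeddings <- embs
    countFrequency(g, ec, cfg$measure)
  })
  ng <- runIteration(g, basics, basics, cfg)
  target <- sort(c("a b", "a c", "b c", "b e"))
  hit <- Filter(function(ec) areIsomorphic(ec@representative, target), ng)
  expect_length(hit, 1)
  expect_equal(disjointCount(hit[[1]]), 2)

  # a threshold above every frequency empties the generation
  cfgHigh <- discoveryConfig(4, "edges", alpha = 50)
  expect_length(runIteration(g, basics, basics, cfgHigh), 0)

  # identical join products are stored once per class
  for (ec in ng) {
    keys <- vapply(ec@embeddings, paste, collapse = "|", character(1))
    expect_false(anyDuplicated(keys) > 0)
  }
})

test_that("discovery reproduces the toy-graph frequencies", {
  g <- fig1Graph()
  target <- sort(c("a b", "a c", "b c", "b e"))

  rep2 <- findMotifs(g, discoveryConfig(4, "edges", alpha = 2))
  hit <- Filter(function(ec) areIsomorphic(ec@representative, target),
                reportClasses(rep2))
  expect_length(hit, 1)
  expect_equal(disjointCount(hit[[1]]), 2)

  rep3 <- findMotifs(g, discoveryConfig(4, "edges", alpha = 3))
  expect_length(Filter(function(ec)
    areIsomorphic(ec@representative, target), reportClasses(rep3)), 0)

  # two disjoint 5-cycles: the 5-node cycle motif occurs twice
  ring <- function(p) cbind(p, c(p[-1], p[1]))
  g2 <- MotifNetwork(rbind(ring(letters[1:5]), ring(letters[6:10])))
  rep5 <- findMotifs(g2, discoveryConfig(5, "nodes", alpha = 2,
                                         joinSource = "all"))
  cyc <- Filter(function(ec) patternEdgeCount(ec) == 5,
                reportClasses(rep5))
  expect_length(cyc, 1)
  expect_equal(disjointCount(cyc[[1]]), 2)
})

test_that("reports are sound, bounded, and deterministic", {
  g <- barabasiAlbert(20, 2, seed = 77)
  for (cfg in list(discoveryConfig(4, "nodes", alpha = 2),
                   discoveryConfig(4, "edges", alpha = 2, measure = "F3"),
                   discoveryConfig(4, "edges", alpha = 1,
                                   joinSource = "all"))) {
    rep <- findMotifs(g, cfg)
    expect_true(validateMotifReport(g, rep))
    for (ec in reportClasses(rep)) {
      if (cfg$measure == "F2")
        expect_lte(disjointCount(ec) * patternEdgeCount(ec), numEdges(g))
      else
        expect_lte(disjointCount(ec) * patternNodeCount(ec), numNodes(g))
      # every generated pattern exists in the graph (soundness by
      # construction): its first embedding is a witness
      expect_true(all(ec@embeddings[[1]] %in% edgeKeys(g)))
    }
    rep2 <- findMotifs(g, cfg)
    expect_identical(methods::as(rep, "data.frame"),
                     methods::as(rep2, "data.frame"))
  }
})

test_that("discovery is a sound subset of exhaustive enumeration (diagnostic)", {
  # completeness is not guaranteed; on a tiny graph, everything reported must
  # appear in the exhaustive catalogue with a frequency no larger than exact
  g <- barabasiAlbert(9, 1, seed = 5)   # 9 nodes, 8 edges
  cfg <- discoveryConfig(4, "edges", alpha = 1, joinSource = "all")
  rep <- findMotifs(g, cfg)
  cand <- enumerateConnectedEdgeSets(g, 4)
  for (ec in reportClasses(rep)) {
    matches <- Filter(function(e) areIsomorphic(e, ec@representative), cand)
    expect_gte(length(matches), f1Count(ec))
    expect_lte(disjointCount(ec),
               exactMISSize(oracleOverlapAdjacency(matches, "F2")))
  }
})

test_that("reports serialise to JSON and TSV", {
  g <- fig1Graph()
  rep <- findMotifs(g, discoveryConfig(4, "edges", alpha = 2))
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeMotifReport(rep, jsonPath = jf, tsvPath = tf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$config$alpha, 2)
  expect_length(parsed$patterns, length(reportClasses(rep)))
  expect_equal(parsed$patterns[[1]]$frequency, 2)
  tab <- read.delim(tf)
  expect_equal(tab$frequency[1], 2)
  expect_equal(tab$edges[1], 4)
})
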