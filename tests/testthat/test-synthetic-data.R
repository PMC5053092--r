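# Synthetic generators and the command-line driver.

test_that("Barabasi-Albert graphs have the requested density and shape", {
  g <- barabasiAlbert(100, 2, seed = 7)
  expect_equal(numNodes(g), 100)
  # |E| = C(3,2) + 97*2; mean degree close to 4
  expect_equal(numEdges(g), 3 + 97 * 2)
  expect_gt(mean(nodeDegrees(g)), 3.5)
  expect_lt(mean(nodeDegrees(g)), 4.5)

  # determinism
  expect_identical(edgeKeys(barabasiAlbert(50, 2, seed = 3)),
                   edgeKeys(barabasiAlbert(50, 2, seed = 3)))

  # density 1 gives a connected tree-like graph with about n edges
  t1 <- barabasiAlbert(1000, 1, seed = 11)
  expect_gte(numEdges(t1), 1000 - 3)
  expect_lte(numEdges(t1), 1000)
  expect_equal(numNodes(pruneSmallComponents(t1, 1000)), 1000)  # connected

  # right-skewed degree distribution: hubs dominate the median
  d <- nodeDegrees(barabasiAlbert(500, 2, seed = 13))
  expect_gt(max(d), 3 * median(d))

  expect_error(barabasiAlbert(3, 3), "nNodes > density")
})

test_that("the toy graph is exactly the printed seven-node network", {
  g <- fig1Graph()
  expect_equal(numNodes(g), 7)
  expect_equal(numEdges(g), 8)
  expect_identical(networkNodes(g), letters[1:7])
  expect_equal(unname(nodeDegrees(g)["e"]), 4L)
  expect_identical(edgeKeys(g), fig1Edges())
  tf <- withr::local_tempfile()
  writeEdgeList(g, tf)
  expect_identical(edgeKeys(readEdgeList(tf)), edgeKeys(g))
})

test_that("generated graph pairs are matched in size and non-isomorphic", {
  pairs <- nonisomorphicPairs(15, sizeRange = c(8, 16), density = 1,
                              seed = 5)
  expect_length(pairs, 15)
  for (p in pairs) {
    expect_equal(numNodes(p$g1), numNodes(p$g2))
    expect_equal(numEdges(p$g1), numEdges(p$g2))
    expect_false(igraph::isomorphic(
      igraph::graph_from_edgelist(networkEdges(p$g1), directed = FALSE),
      igraph::graph_from_edgelist(networkEdges(p$g2), directed = FALSE)))
  }
  rate <- degreeVectorFilterRate(pairs)
  expect_gte(rate, 0)
  expect_lte(rate, 1)
})

test_that("the command-line driver runs the pipeline end to end", {
  el <- withr::local_tempfile()
  writeEdgeList(fig1Graph(), el)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  man <- withr::local_tempfile(fileext = ".json")

  code <- suppressMessages(runMotifCLI(c(
    "find-motifs", "--graph", el, "--size", "4", "--size-mode", "edges",
    "--alpha", "2", "--measure", "F2", "--out-tsv", tsv,
    "--out-json", json, "--manifest", man)))
  expect_equal(code, 0L)
  tab <- read.delim(tsv)
  expect_true(any(tab$edges == 4 & tab$frequency == 2))
  expect_true(file.exists(man))

  # identical rerun gives byte-identical outputs
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  suppressMessages(runMotifCLI(c(
    "find-motifs", "--graph", el, "--size", "4", "--size-mode", "edges",
    "--alpha", "2", "--measure", "F2", "--out-tsv", tsv2)))
  expect_identical(readLines(tsv), readLines(tsv2))

  # invalid alpha is a usage error (exit 1)
  expect_equal(suppressMessages(runMotifCLI(c(
    "find-motifs", "--graph", el, "--size", "4", "--alpha", "0"))), 1L)

  # impossible threshold: valid but empty (exit 2)
  expect_equal(suppressMessages(runMotifCLI(c(
    "find-motifs", "--graph", el, "--size", "4", "--size-mode", "edges",
    "--alpha", "99"))), 2L)

  # significance subcommand, within mode
  out <- withr::local_tempfile(fileext = ".json")
  code <- suppressMessages(runMotifCLI(c(
    "significance", "--graph", el, "--size", "3", "--size-mode", "edges",
    "--mode", "within", "--out", out)))
  expect_equal(code, 0L)
  expect_true(file.exists(out))

  # simulate subcommand writes a readable edge list
  ba <- withr::local_tempfile()
  code <- suppressMessages(runMotifCLI(c(
    "simulate", "ba", "--nodes", "30", "--density", "2", "--seed", "4",
    "--out", ba)))
  expect_equal(code, 0L)
  expect_equal(numNodes(readEdgeList(ba)), 30)

  # count-pattern locates the toy chordal pattern
  pat <- withr::local_tempfile()
  writeLines(c("1 2", "1 3", "2 3", "2 4"), pat)
  code <- suppressMessages(runMotifCLI(c(
    "count-pattern", "--graph", el, "--pattern", pat)))
  expect_equal(code, 0L)
})
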