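test_that("opposite records collapse to one reciprocal edge and duplicates dedupe", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\ta"), tf)
  g <- readEdgeList(tf)
  s <- edgeTypeSummary(g)
  expect_equal(s$reciprocalDyads, 1L)
  expect_equal(s$pureArcs, 0L)

  writeLines(c("a\tb", "a\tb"), tf)
  g2 <- readEdgeList(tf)
  expect_equal(edgeTypeSummary(g2)$pureArcs, 1L)
  expect_equal(edgeTypeSummary(g2)$orderedArcs, 1L)

  writeLines("a\tb", tf)
  expect_equal(edgeTypeSummary(readEdgeList(tf))$pureArcs, 1L)
})

test_that("malformed and self-arc records are rejected with a line number", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "brokenline"), tf)
  expect_error(readEdgeList(tf), "line 2")
  writeLines(c("# comment", "a\ta"), tf)
  expect_error(readEdgeList(tf), "self-arc at line 2")
  expect_error(DirectedNetwork(cbind("x", "x")), "self-arc")
})

test_that("neighbor sets partition the neighborhood by edge type", {
  ns <- neighborSets(pathGraph(), "b")
  expect_equal(ns$out, "c")
  expect_equal(ns$`in`, "a")
  expect_equal(ns$rec, character(0))

  g <- DirectedNetwork(cbind(c("a", "b", "a", "c"), c("b", "a", "c", "a")))
  ns2 <- neighborSets(g, "a")
  expect_setequal(ns2$rec, c("b", "c"))
  expect_equal(ns2$out, character(0))
  expect_equal(ns2$`in`, character(0))

  expect_error(neighborSets(g, "zz"), "unknown vertex")
})

test_that("typed adjacency is an exact partition consistent with a pair scan", {
  for (s in 1:5) {
    g <- randomDigraph(8, pArc = 0.5, pRec = 0.4, seed = 100 + s)
    ta <- typedAdjacency(g)
    A <- adjacencyMatrix(g)
    expect_identical(ta$`in`, t(ta$out))
    expect_identical(ta$rec, t(ta$rec))
    expect_true(all(diag(ta$out) == 0) && all(diag(ta$rec) == 0))
    ## disjoint supports, union reconstructs adjacency
    expect_true(all(ta$out + ta$`in` + ta$rec <= 1))
    expect_identical(ta$out + ta$rec, A)
    ## definition scan per pair
    n <- numVertices(g)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      expect_identical(ta$out[i, j], (A[i, j] == 1L && A[j, i] == 0L) * 1L)
      expect_identical(ta$rec[i, j], (A[i, j] == 1L && A[j, i] == 1L) * 1L)
    }
    ## row sums match neighbor-set cardinalities
    for (i in seq_len(n)) {
      ns <- neighborSets(g, i)
      expect_equal(sum(ta$out[i, ]), length(ns$out))
      expect_equal(sum(ta$`in`[i, ]), length(ns$`in`))
      expect_equal(sum(ta$rec[i, ]), length(ns$rec))
    }
  }
})

test_that("pure arcs + 2 x reciprocal dyads equals the ordered arc count", {
  for (s in 1:10) {
    g <- randomDigraph(12, pArc = 0.4, pRec = 0.5, seed = s)
    es <- edgeTypeSummary(g)
    expect_equal(es$pureArcs + 2L * es$reciprocalDyads, es$orderedArcs)
    expect_equal(es$orderedArcs, nrow(arcs(g)))
  }
})

test_that("both file formats round-trip, including isolated vertices", {
  g <- randomDigraph(9, pArc = 0.3, pRec = 0.5, seed = 11)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(g, tf, format = "edgelist")
  g2 <- readEdgeList(tf)
  expect_identical(vertexLabels(g2), vertexLabels(g))
  expect_identical(adjacencyMatrix(g2), adjacencyMatrix(g))

  cf <- withr::local_tempfile(fileext = ".csv")
  writeNetwork(g, cf, format = "adjacency")
  g3 <- readAdjacencyMatrix(cf)
  expect_identical(adjacencyMatrix(g3), adjacencyMatrix(g))

  ## empty network: vertex set survives via the vertices comment
  e <- DirectedNetwork(labels = c("x", "y", "z"))
  writeNetwork(e, tf)
  e2 <- readEdgeList(tf)
  expect_identical(vertexLabels(e2), c("x", "y", "z"))
  expect_equal(nrow(arcs(e2)), 0L)

  ## a reciprocal dyad emits both ordered records
  r <- DirectedNetwork(cbind(c("a", "b"), c("b", "a")))
  writeNetwork(r, tf)
  body <- grep("^[^#]", readLines(tf), value = TRUE)
  expect_setequal(body[-1], c("a\tb", "b\ta"))
})

test_that("a weight column is preserved for downstream preprocessing", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.5", "b\tc\t-0.25"), tf)
  g <- readEdgeList(tf)
  w <- attr(g, "weights")
  expect_equal(unname(w[c("a->b", "b->c")]), c(0.5, -0.25))
  ## binary analysis ignores it
  expect_equal(unname(degreeCounts(g, "b")), c(1, 1, 0))
})

test_that("validity catches malformed networks", {
  expect_error(new("DirectedNetwork", labels = c("a", "a"),
                   arcs = matrix(integer(), ncol = 2L)),
               "unique")
  expect_error(new("DirectedNetwork", labels = c("a", "b"),
                   arcs = matrix(c(1L, 1L), ncol = 2L)),
               "self-arcs")
  expect_error(new("DirectedNetwork", labels = c("a", "b"),
                   arcs = matrix(c(1L, 1L, 2L, 2L), ncol = 2L)),
               "duplicate")
})
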