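test_that("degree counts equal typed neighbor-set cardinalities", {
  expect_equal(unname(degreeCounts(outStar(3), "hub")), c(3, 0, 0))
  rt <- reciprocalTriangle()
  expect_equal(unname(degreeCounts(rt, "a")), c(0, 0, 2))
  g <- randomDigraph(12, 0.4, 0.3, seed = 21)
  for (i in seq_len(12)) {
    ns <- neighborSets(g, i)
    expect_equal(unname(degreeCounts(g, i)),
                 c(length(ns$out), length(ns$`in`), length(ns$rec)))
  }
})

test_that("typed wedge counts are induced, symmetric, and match the oracle", {
  ## path a->b->c: one (out,in) wedge at the center only
  W <- typedWedgeCounts(pathGraph(), "b")
  expect_equal(W["out", "in"], 1)
  expect_equal(W["in", "out"], 1)
  expect_equal(sum(W), 2)  # the same wedge under both orderings

  ## directed 3-cycle: every neighbor pair is adjacent, so nothing induced
  for (v in c("a", "b", "c"))
    expect_equal(sum(typedWedgeCounts(cycleGraph3(), v)), 0)

  for (s in 1:5) {
    g <- randomDigraph(10, 0.4, 0.4, seed = 500 + s)
    for (i in seq_len(10)) {
      W <- typedWedgeCounts(g, i)
      expect_equal(W, t(W))
    }
  }
})

test_that("typed triangle counts follow the orientation convention", {
  ## {i->h, h->j, i<->j} is the (out, in, rec) triangle
  g <- DirectedNetwork(cbind(c("i", "h", "i", "j"), c("h", "j", "j", "i")))
  Tt <- typedTriangleCounts(g, "i")
  expect_equal(Tt["out", "in", "rec"], 1)
  expect_equal(sum(Tt), 2)  # the triangle under both (h, j) orderings

  ## all-reciprocal triangle: only the (rec, rec, rec) cell, both orderings
  Tt2 <- typedTriangleCounts(reciprocalTriangle(), "a")
  expect_equal(Tt2["rec", "rec", "rec"], 2)
  expect_equal(sum(Tt2), 2)
})

test_that("wedge class counts are counted once at the center", {
  expect_equal(unname(wedgeClassCounts(outStar(3), "hub")["W_out"]), 3)
  expect_equal(unname(wedgeClassCounts(pathGraph(), "b")["W_path"]), 1)
  ## endpoints are not centers
  expect_equal(sum(wedgeClassCounts(pathGraph(), "a")), 0)
  expect_equal(sum(wedgeClassCounts(pathGraph(), "c")), 0)
})

test_that("triangle class counts distinguish the seven classes", {
  for (v in c("a", "b", "c")) {
    expect_equal(unname(triangleClassCounts(reciprocalTriangle(), v)["T_rec"]), 1)
    expect_equal(unname(triangleClassCounts(cycleGraph3(), v)["T_cycle"]), 1)
    expect_equal(sum(triangleClassCounts(cycleGraph3(), v)), 1)
    expect_equal(unname(triangleClassCounts(transitiveTriangle(), v)["T_acyclic"]), 1)
  }
})

test_that("signature vectors concatenate the blocks in canonical order", {
  g <- DirectedNetwork(cbind(c("a", "b"), c("b", "c")),
                       labels = c("a", "b", "c", "iso"))
  expect_equal(unname(signatureVector(g, "iso")), rep(0, 16))
  f <- signatureVector(reciprocalTriangle(), "a")
  expect_equal(unname(f),
               c(0, 0, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1))
  S <- signatureMatrix(g)
  expect_identical(vertexLabels(S), vertexLabels(g))
  expect_identical(colnames(signatureCounts(S)), signatureClassNames())
})

test_that("block normalization handles regular and degenerate blocks", {
  f <- c(2, 1, 1, rep(0, 6), rep(1, 7))
  nf <- normalizedSignature(f)
  expect_equal(unname(nf[1:3]), c(0.5, 0.25, 0.25))
  expect_equal(unname(attr(nf, "degenerate")),
               c(FALSE, TRUE, FALSE))
  z <- normalizedSignature(rep(0, 16))
  expect_equal(as.vector(z), rep(0, 16))
  expect_true(all(attr(z, "degenerate")))
})

test_that("conservation identities hold on random digraphs", {
  for (s in 1:10) {
    g <- randomDigraph(12, pArc = 0.1 + 0.08 * s, pRec = (s %% 4) / 3,
                       seed = 900 + s)
    cnt <- signatureCounts(signatureMatrix(g))
    es <- edgeTypeSummary(g)
    expect_equal(sum(cnt[, "d_out"]), es$pureArcs)
    expect_equal(sum(cnt[, "d_in"]), es$pureArcs)
    expect_equal(sum(cnt[, "d_rec"]), 2 * es$reciprocalDyads)
    ## wedges have a unique center; triangles touch three vertices
    oc <- signatureCounts(oracleSignatureMatrix(g))
    for (cl in signatureClassNames()[4:9])
      expect_equal(sum(cnt[, cl]), sum(oc[, cl]))
    for (cl in signatureClassNames()[10:16])
      expect_equal(sum(cnt[, cl]) %% 3, 0)
  }
})

test_that("the complete reciprocal graph has no wedges and all reciprocal triangles", {
  g <- completeReciprocal(6)
  cnt <- signatureCounts(signatureMatrix(g))
  expect_true(all(cnt[, 4:9] == 0))
  expect_true(all(cnt[, "T_rec"] == choose(5, 2)))
  expect_true(all(cnt[, setdiff(signatureClassNames()[10:16], "T_rec")] == 0))
})

test_that("signature matrix TSV round-trips", {
  g <- randomDigraph(8, 0.4, 0.3, seed = 77)
  S <- signatureMatrix(g)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeSignatureMatrix(S, tf, header = "fixture")
  S2 <- readSignatureMatrix(tf)
  expect_equal(signatureCounts(S2), signatureCounts(S))
})
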