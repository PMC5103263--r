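## Build a GCM whose (1,2) entry (and its mirror) is `value`, rest benign.
gcmWithEntry <- function(value, defined12 = TRUE) {
  C <- diag(16)
  C[1, 2] <- C[2, 1] <- if (defined12) value else NA
  D <- matrix(TRUE, 16, 16)
  if (!defined12) D[1, 2] <- D[2, 1] <- FALSE
  dimnames(C) <- dimnames(D) <- list(signatureClassNames(),
                                     signatureClassNames())
  new("GraphletCorrelationMatrix", correlations = C, defined = D,
      nVertices = 10L)
}

test_that("consensus percentages are direct subject counts", {
  gcms <- lapply(c(0.8, 0.9, 0.75, -0.2, 0.71), gcmWithEntry)
  cons <- consensus(gcms, threshold = 0.7)
  expect_equal(consensusPercent(cons, "positive")[1, 2], 80)
  expect_equal(consensusPercent(cons, "negative")[1, 2], 0)
  expect_equal(numSubjects(cons), 5L)

  neg <- lapply(rep(-0.9, 4), gcmWithEntry)
  expect_equal(consensusPercent(consensus(neg), "negative")[1, 2], 100)
  ## diagonal: all subjects have defined unit diagonals
  expect_true(all(diag(consensusPercent(cons, "positive")) == 100))
})

test_that("undefined subject entries count as not significant, denominator fixed", {
  gcms <- c(lapply(rep(0.9, 3), gcmWithEntry),
            list(gcmWithEntry(0, defined12 = FALSE)))
  cons <- consensus(gcms)
  expect_equal(consensusPercent(cons, "positive")[1, 2], 75)
})

test_that("a single subject reproduces its mask scaled to 0/100", {
  g <- gcmWithEntry(-0.95)
  cons <- consensus(list(g))
  m <- significanceMask(g)
  expect_equal(consensusPercent(cons, "positive"),
               100 * (m == 1L) + 0, ignore_attr = TRUE)
  expect_equal(consensusPercent(cons, "negative"),
               100 * (m == -1L) + 0, ignore_attr = TRUE)
})

test_that("consensus is invariant to subject order", {
  vals <- c(0.9, -0.8, 0.75, 0.1, -0.95, 0.72)
  gcms <- lapply(vals, gcmWithEntry)
  c1 <- consensus(gcms)
  c2 <- consensus(rev(gcms))
  expect_equal(consensusPercent(c1, "positive"),
               consensusPercent(c2, "positive"))
  expect_equal(consensusPercent(c1, "negative"),
               consensusPercent(c2, "negative"))
})

test_that("consensus mask is strict at the boundary and monotone in the cutoff", {
  gcms <- lapply(c(0.9, 0.9, 0.9, 0.1, 0.1), gcmWithEntry)  # exactly 60%
  cons <- consensus(gcms)
  expect_equal(consensusPercent(cons, "positive")[1, 2], 60)
  expect_equal(consensusMask(cons, minPercent = 60)[1, 2], 0L)
  expect_equal(consensusMask(cons, minPercent = 59)[1, 2], 1L)

  gcms2 <- lapply(c(0.9, 0.9, 0.9, 0.9, 0.1), gcmWithEntry)  # 80%
  cons2 <- consensus(gcms2)
  expect_equal(consensusMask(cons2, minPercent = 60)[1, 2], 1L)
  ## raising the cutoff can only turn entries to zero
  for (p in c(10, 30, 50, 70)) {
    lowMask <- consensusMask(cons2, minPercent = p)
    for (q in seq(p + 10, 90, by = 10)) {
      highMask <- consensusMask(cons2, minPercent = q)
      expect_true(all(highMask == 0L | highMask == lowMask))
    }
  }
  expect_error(consensusMask(cons2, minPercent = 0), "\\(0, 100\\]")
})

test_that("regional comparison flags planted outliers and nothing else when flat", {
  set.seed(515)
  labels <- paste0("R", 1:12)
  mkRec <- function(id, extraOutFrom = NULL) {
    exc <- randomDigraph(12, 0.3, 0.2, labels = labels)
    base <- randomDigraph(12, 0.3, 0.2, labels = labels)
    if (!is.null(extraOutFrom)) {
      others <- setdiff(labels, extraOutFrom)
      extra <- cbind(rep(extraOutFrom, length(others)), others)
      base <- DirectedNetwork(rbind(arcs(base),
                                    cbind(match(extra[, 1], labels),
                                          match(extra[, 2], labels))),
                              labels = labels)
    }
    cohortRecord(id, exc, base)
  }
  ## identical halves: every delta is zero, nothing flagged
  flat <- lapply(1:4, function(s) {
    g <- randomDigraph(12, 0.3, 0.2, labels = labels)
    cohortRecord(s, g, g)
  })
  resFlat <- regionalClassComparison(flat, class = "W_out")
  expect_equal(resFlat$percentInhibitoryGreater, 0)
  expect_equal(resFlat$percentExcitatoryGreater, 0)

  ## one region with a large planted inhibitory out-excess
  planted <- lapply(1:6, function(s) mkRec(s, extraOutFrom = "R1"))
  res <- regionalClassComparison(planted, class = "W_out")
  tab <- res$table
  expect_equal(tab$verdict[tab$region == "R1"], "greater_in_inhibitory")

  expect_error(regionalClassComparison(planted[1]), "at least two")
  expect_error(regionalClassComparison(planted, class = "nope"),
               "unknown signature class")
})

test_that("cohort records insist on one shared vertex set", {
  a <- randomDigraph(5, 0.5, 0.2, seed = 1)
  b <- randomDigraph(6, 0.5, 0.2, seed = 2)
  expect_error(cohortRecord("s", a, b), "vertex set")
})

test_that("cohort manifest round-trips through disk", {
  dir <- withr::local_tempdir()
  labels <- paste0("R", 1:8)
  recs <- lapply(1:3, function(s) {
    exc <- randomDigraph(8, 0.5, 0.3, seed = 10 + s, labels = labels)
    inh <- randomDigraph(8, 0.4, 0.3, seed = 20 + s, labels = labels)
    writeNetwork(exc, file.path(dir, paste0("s", s, "_exc.tsv")))
    writeNetwork(inh, file.path(dir, paste0("s", s, "_inh.tsv")))
    list(exc = exc, inh = inh)
  })
  manifest <- file.path(dir, "manifest.tsv")
  write.table(data.frame(subject_id = paste0("s", 1:3),
                         excitatory_path = paste0("s", 1:3, "_exc.tsv"),
                         inhibitory_path = paste0("s", 1:3, "_inh.tsv")),
              manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  loaded <- readCohortManifest(manifest)
  expect_length(loaded, 3L)
  expect_identical(adjacencyMatrix(loaded[[2]]$excitatory),
                   adjacencyMatrix(recs[[2]]$exc))
  expect_identical(adjacencyMatrix(loaded[[3]]$inhibitory),
                   adjacencyMatrix(recs[[3]]$inh))
})
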