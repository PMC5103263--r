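## Fixed integer signature table used for the direct-formula comparison.
fixedSignatureTable <- function() {
  set.seed(424)
  m <- matrix(sample(0:9, 5 * 16, replace = TRUE), 5, 16)
  rownames(m) <- paste0("v", 1:5)
  m
}

## Textbook Pearson coefficient, written out independently of stats::cor.
pearsonByHand <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

test_that("GCM entries match the direct Pearson formula", {
  m <- fixedSignatureTable()
  gcm <- graphletCorrelationMatrix(m)
  C <- correlations(gcm)
  for (a in 1:16) for (b in 1:16) {
    expected <- pearsonByHand(m[, a], m[, b])
    expect_equal(C[a, b], expected, tolerance = 1e-12)
  }
})

test_that("identical, negated, and constant columns behave as defined", {
  m <- fixedSignatureTable()
  m[, 2] <- m[, 1]          # identical nonconstant columns
  m[, 3] <- -m[, 1] + 20    # negation (shifted to stay nonnegative)
  m[, 4] <- 7               # zero variance
  gcm <- graphletCorrelationMatrix(m)
  C <- correlations(gcm)
  expect_equal(C[1, 2], 1.0)
  expect_equal(C[1, 3], -1.0)
  expect_true(all(is.na(C[4, ])))
  expect_false(any(definedEntries(gcm)[4, ]))
  expect_true(all(diag(C)[-4] == 1))
})

test_that("GCM is symmetric, permutation-invariant and scale-invariant", {
  g <- randomDigraph(25, 0.3, 0.4, seed = 31)
  S <- signatureMatrix(g)
  C <- correlations(graphletCorrelationMatrix(S))
  expect_equal(C, t(C))
  expect_true(all(abs(C[!is.na(C)]) <= 1 + 1e-12))

  cnt <- signatureCounts(S)
  perm <- sample(nrow(cnt))
  C2 <- correlations(graphletCorrelationMatrix(cnt[perm, ]))
  expect_equal(C2, C)

  scaled <- cnt
  scaled[, 5] <- scaled[, 5] * 3  # positive column scaling
  C3 <- correlations(graphletCorrelationMatrix(scaled))
  expect_equal(C3, C)
})

test_that("fewer than three vertices is an insufficient-data error", {
  m <- matrix(1, 2, 16, dimnames = list(c("a", "b"), NULL))
  expect_error(graphletCorrelationMatrix(m), "at least 3")
})

test_that("significance mask uses strict inequalities and maps NA to 0", {
  C <- matrix(0, 16, 16)
  C[1, 2] <- C[2, 1] <- 0.7     # exactly at threshold: not significant
  C[1, 3] <- C[3, 1] <- 0.71
  C[2, 3] <- C[3, 2] <- -0.71
  C[4, 5] <- C[5, 4] <- NA
  diag(C) <- 1
  D <- !is.na(C)
  dimnames(C) <- dimnames(D) <- list(signatureClassNames(),
                                     signatureClassNames())
  gcm <- new("GraphletCorrelationMatrix", correlations = C, defined = D,
             nVertices = 10L)
  m <- significanceMask(gcm, threshold = 0.7)
  expect_equal(m[1, 2], 0L)
  expect_equal(m[1, 3], 1L)
  expect_equal(m[2, 3], -1L)
  expect_equal(m[4, 5], 0L)
  expect_true(all(diag(m) == 1L))
  expect_error(significanceMask(gcm, threshold = 0), "in \\(0, 1\\]")
})

test_that("vertex similarity is scale-free and flags constant rows", {
  m <- fixedSignatureTable()
  m[2, ] <- 2 * m[1, ]
  m[3, ] <- 4
  S <- new("SignatureMatrix",
           counts = `colnames<-`(m, signatureClassNames()))
  expect_equal(vertexSimilarity(S, 1, 1), 1.0)
  expect_equal(vertexSimilarity(S, 1, 2), 1.0)
  expect_true(is.na(vertexSimilarity(S, 1, 3)))
})

test_that("Ward clustering recovers planted signature clusters", {
  set.seed(99)
  centers <- list(c(rep(40, 3), rep(2, 6), rep(1, 7)),
                  c(rep(2, 3), rep(40, 6), rep(1, 7)),
                  c(rep(1, 3), rep(2, 6), rep(40, 7)))
  rows <- do.call(rbind, lapply(1:3, function(k)
    t(replicate(10, pmax(0, round(centers[[k]] + rnorm(16, sd = 2)))))))
  rownames(rows) <- paste0("v", seq_len(nrow(rows)))
  colnames(rows) <- signatureClassNames()
  S <- new("SignatureMatrix", counts = rows)
  cl <- clusterVertices(S, k = 3)
  planted <- rep(1:3, each = 10)
  ## perfect recovery up to label permutation
  tab <- table(cl$clusters, planted)
  expect_equal(sum(apply(tab, 1, max)), 30)
  expect_setequal(cl$order, rownames(rows))
})

test_that("GCM CSV round-trips with empty cells for undefined entries", {
  m <- fixedSignatureTable()
  m[, 7] <- 5
  gcm <- graphletCorrelationMatrix(m)
  tf <- withr::local_tempfile(fileext = ".csv")
  writeGCM(gcm, tf, header = "fixture")
  gcm2 <- readGCM(tf)
  expect_equal(correlations(gcm2), correlations(gcm), tolerance = 1e-12)
  expect_equal(definedEntries(gcm2), definedEntries(gcm))
})
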