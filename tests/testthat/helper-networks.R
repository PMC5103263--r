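## Small named fixtures built in code.

pathGraph <- function() DirectedNetwork(cbind(c("a", "b"), c("b", "c")))

cycleGraph3 <- function()
  DirectedNetwork(cbind(c("a", "b", "c"), c("b", "c", "a")))

transitiveTriangle <- function()
  DirectedNetwork(cbind(c("a", "a", "b"), c("b", "c", "c")))

reciprocalTriangle <- function()
  DirectedNetwork(cbind(c("a", "b", "a", "c", "b", "c"),
                        c("b", "a", "c", "a", "c", "b")))

outStar <- function(k = 3) {
  leaves <- paste0("l", seq_len(k))
  DirectedNetwork(cbind(rep("hub", k), leaves))
}

## Complete reciprocal graph K_n with every dyad reciprocal.
completeReciprocal <- function(n) {
  pr <- t(combn(paste0("v", seq_len(n)), 2))
  DirectedNetwork(rbind(pr, pr[, 2:1]))
}

expect_signature_equals_oracle <- function(g) {
  fast <- signatureCounts(signatureMatrix(g))
  slow <- signatureCounts(oracleSignatureMatrix(g))
  expect_equal(fast, slow)
}
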