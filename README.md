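# digraphlets

Graphlet analysis probes the local structure of a network through small
induced subgraphs, without reference to any null model. **digraphlets**
extends this to *directed* networks with reciprocal edges: for every
vertex it counts the 2-node and 3-node directed graphlets starting there,
summarizes them in a 16-dimensional *signature vector*, and condenses the
network into a 16 × 16 *graphlet correlation matrix* (GCM). The package
targets effective (causal) brain connectivity — signed, directed networks
estimated with Granger causality between brain regions — but works on any
simple directed graph.

## The method

A simple digraph is treated as having three edge types with respect to a
vertex *i*: pure out (*i* → *j* only), pure in (*j* → *i* only), and
reciprocal (*i* ↔ *j*, a pair of opposite arcs treated as one
bidirectional link). From these:

* **Degrees** d⁺, d⁻, d° — the 2-node graphlets at *i*.
* **Wedges** W_i(α, β) — induced 3-node graphlets with two edges, both
  incident to center *i*, the third pair non-adjacent. The 9 ordered
  typed wedges reduce to **6 isomorphism classes**
  (W^(out), W^(in), W^(path), W^(out∘), W^(in∘), W^(rec)).
* **Triangles** T_i(α, β, γ) — 3-node graphlets with all pairs adjacent,
  counted by typed-adjacency matrix products; the 27 ordered typed
  triangles reduce to **7 isomorphism classes**.

The 3 + 9 + 27 = 39 typed quantities per vertex reduce to the
**16-dimensional signature vector** F_i = [d_i, W_i, T_i]. Stacking all
vertices gives the N × 16 signature matrix; Pearson correlations between
its columns give the GCM. Across a cohort, the package reports the
percentage of subjects in which each GCM entry is significant
(|r| > 0.7 by default) and masks entries shared by more than 60 % of
subjects. A direction-randomization null (each connected pair reassigned
out / in / reciprocal with probability ⅓, skeleton preserved) quantifies
what the signatures owe to edge directions: under it the normalized
blocks converge to (⅓, ⅓, ⅓), (1, 1, 2, 2, 2, 1)/9 and
(6, 2, 3, 3, 6, 6, 1)/27.

For signed weighted connectivity (e.g. GCA coefficients), positive and
negative weights are split into excitatory and inhibitory networks, each
pruned to the smallest proportion of strongest weights such that ≥ 99 %
of the vertices sit in the largest weakly connected component and every
vertex there keeps at least 2 ln N distinct neighbors.

Every count is pinned against a brute-force oracle that enumerates all
3-subsets and classifies induced subgraphs by exhaustive
canonical-form minimization.

## Worked example

```r
library(digraphlets)

g <- randomDigraph(60, pArc = 0.15, pRec = 0.3, seed = 11)
g
#> DirectedNetwork with 60 vertices and 334 arcs
#>   pure arcs: 182  reciprocal dyads: 76

S <- signatureMatrix(g)
signatureCounts(S)[1:3, c(1:4, 10, 16)]
#>    d_out d_in d_rec W_out T_acyclic T_rec
#> v1     3    2     7     3         0     0
#> v2     4    5     0     6         1     0
#> v3     3    5     1     3         2     0

gcm <- graphletCorrelationMatrix(S)
round(correlations(gcm)[1:4, 1:4], 3)
#>        d_out   d_in  d_rec  W_out
#> d_out  1.000  0.056 -0.070  0.910
#> d_in   0.056  1.000 -0.097  0.091
#> d_rec -0.070 -0.097  1.000 -0.016
#> W_out  0.910  0.091 -0.016  1.000
sum(significanceMask(gcm) == 1)   # entries with r > 0.7
#> [1] 28
```

The out-degree column correlates strongly with the out-wedge column
(r = 0.91 > 0.7, hence flagged significant): vertices sending many arcs
also center many out-wedges in this random graph.

A signed cohort, split, pruned and aggregated:

```r
cohort <- gcaCohort(nRegions = 116, subjects = 5, seed = 11)
pr <- pruneNetwork(splitBySign(cohort[[1]])$excitatory)
pr$p; pr$k
#> [1] 0.1372527
#> [1] 1102
pr$criteria
#> $componentSize        116     (required 115)
#> $minDegree            10      (required 9.50718 = 2 ln 116)

gcms <- lapply(cohort, function(s) graphletCorrelationMatrix(
  signatureMatrix(pruneNetwork(splitBySign(s)$excitatory)$network)))
consensus(gcms)
#> ConsensusMatrix over 5 subjects (|r| > 0.7 )
#>   entries with positive consensus > 60%: 43
#>   entries with negative consensus > 60%: 0
```

A thin command-line interface over the same functions lives at
`inst/scripts/digraphlets` (subcommands `count`, `gcm`, `cohort`,
`split`, `prune`, `flip`, `simulate`, `enumerate`).

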