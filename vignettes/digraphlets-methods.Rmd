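---
title: "Directed graphlet signatures: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed graphlet signatures: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digraphlets)
```

## The model

A simple directed graph is viewed through its unordered vertex pairs,
each in one of four states: absent, pure arc in either orientation, or
reciprocal (both arcs, treated as a single bidirectional edge). With
respect to a reference vertex $i$ every adjacent neighbor therefore has
one of three types — out, in, or reciprocal — and the typed adjacency
indicators $A^{out}, A^{in} = (A^{out})^T, A^{rec}$ partition the
adjacency matrix exactly.

Graphlets here are *induced*, weakly connected subgraphs on 2 or 3
vertices. Per vertex the package counts:

* the three degrees $d^{out}, d^{in}, d^{rec}$ (2-node graphlets);
* induced wedges centered at $i$: ordered neighbor pairs $(h, j)$ with
  $h$ of type $\alpha$, $j$ of type $\beta$, and $h, j$ non-adjacent.
  The subtraction of closed (adjacent) pairs is what makes the count an
  induced-graphlet count; on a directed 3-cycle every wedge count is
  zero. The $3^2$ ordered typed counts collapse onto 6 isomorphism
  classes; same-type counts are halved (they enumerate ordered pairs)
  and the halving asserts evenness rather than rounding;
* triangles containing $i$: $T_i(\alpha,\beta,\gamma) = \sum_j
  A^{\gamma}_{ij} (A^{\alpha} (A^{\beta})^T)_{ij}$, with the edges
  $i\!-\!h$ and $i\!-\!j$ typed with respect to $i$ and $h\!-\!j$ with
  respect to $j$. Each triangle at $i$ is visited by exactly two ordered
  $(h, j)$ assignments, both landing in the same isomorphism class, so
  class sums are halved (again with an evenness assertion). The $3^3$
  typed counts collapse onto 7 classes.

The resulting 16-vector (3 degrees, 6 wedge classes, 7 triangle classes)
is the vertex signature; the $N \times 16$ stack is the signature
matrix; Pearson correlations between its columns form the graphlet
correlation matrix (GCM).

### Conventions the counts depend on

* **Wedges belong to their center.** Both defining neighbor sets are
  neighbor sets of $i$; wedge endpoints accumulate nothing. Summed over
  vertices, each induced wedge is counted exactly once. Triangles, by
  contrast, are counted once per incident vertex, so class totals summed
  over vertices are three times the number of triangles.
* **Class-to-type maps are derived, not transcribed.** The assignment of
  each of the 27 ordered triangle types to its class is computed at
  first use by building the typed triangle and canonicalizing it
  (exhaustive minimization over the 6 vertex permutations of a 2-bit
  pair-state encoding). The same canonical forms drive the brute-force
  oracle and the class enumeration, so the three routes cannot drift
  apart silently.
* **Out/in naming of the single-dyad acyclic triangle classes.**
  `T_out_rec` is the class whose third vertex *sends* pure arcs to both
  dyad members, `T_in_rec` the one that *receives* from both. Swapping
  the two names would permute two signature coordinates and change no
  count; the package fixes the convention above once.

## The oracle and what "correct" means here

`oracleSignature()` classifies every induced 3-subgraph by canonical
form, independently of the matrix-product path. The test suite pins the
fast path to the oracle exactly — all 16 coordinates, all vertices — on
more than 200 seeded random digraphs with $n \le 12$ spanning arc
probabilities 0.1–0.9 and reciprocity 0–1, and checks conservation
identities (degree sums against arc counts, wedge/triangle class totals
against an independent global triple census). Exact integer agreement,
not tolerance-based, is the acceptance notion for all counting code.

## The direction-flip null

`flipDirections()` reassigns every connected pair one of the three
orientation states uniformly and independently, preserving the
undirected skeleton exactly. Because non-adjacency is also preserved,
each vertex's block totals (degree; induced wedges at the center;
triangles) are invariant across flips, which makes the normalized
signature an unbiased estimator of the class probabilities. Those
probabilities are themselves derived in code from the labeled-type class
sizes of the enumeration — degrees $(1,1,1)/3$, wedges
$(1,1,2,2,2,1)/9$, triangles $(6,2,3,3,6,6,1)/27$ — and the Monte-Carlo
convergence check (default study size: a seeded $n = 60$ skeleton, 2000
flips) must sit within 4 standard errors componentwise.

## GCM, significance and cohort consensus

* **Zero-variance columns.** Sparse networks routinely lack a class
  everywhere (no directed 3-cycles, say). Pearson's coefficient is
  undefined there; the package stores `NA` with an explicit
  defined/undefined flag. Imputing 0 would manufacture confident
  "non-significance" out of nothing, so it is never done. In consensus
  aggregation an undefined subject entry counts as *not significant*
  with the denominator fixed at the cohort size, so one degenerate
  subject cannot silently shrink the cohort.
* **Strict thresholds.** Significance is $r > 0.7$ or $r < -0.7$,
  strictly; consensus requires *more than* 60 % of subjects, strictly.
  Both cutoffs are arguments with these defaults.
* **No multiplicity correction** is applied across the 120 distinct GCM
  entries; the consensus-across-subjects step is the method's own guard
  against subject-level noise.
* **Clustering scale.** Ward (`ward.D2`) clustering of vertices uses
  Euclidean distances on `log1p`-transformed signatures by default:
  graphlet counts are heavy-tailed and raw distances are dominated by
  the degree block. Raw-count distances remain available
  (`scale = "raw"`).

## Regional excitatory-vs-inhibitory comparison

For a chosen signature class the package computes, per region, the
across-subject mean difference $\Delta$ = inhibitory count − excitatory
count and labels regions with a significant excess either way at level
$\alpha = 0.05$. Two strategies are implemented:

* `strategy = "region"` (default): a per-region Student-$t$ confidence
  interval of the mean difference across subjects; a region is labeled
  when its interval excludes zero.
* `strategy = "population"`: a single normal interval
  $\mathrm{mean} \pm z_{1-\alpha/2}\,\mathrm{sd}$ of the across-region
  distribution, with regions outside it labeled.

The per-region strategy is the default on arithmetic grounds: the
fraction of regions outside a mean $\pm 1.96\,$sd band of their own
distribution is bounded by $1/1.96^2 \approx 26\%$ for *any*
distribution (Chebyshev), so a population-band rule can never label a
large share of regions — yet the scientific use case is precisely to
report substantial fractions of regions with an excess in one condition,
and a planted 30 % excess is mathematically invisible to the population
rule even at zero noise (the planted regions inflate the band past
themselves). The per-region interval has no such ceiling and recovers
planted excesses at their planted rate, which is how the suite tests it.
Regions with zero variance across subjects are decided by the sign of
their mean difference (a collapsed interval).

## Preprocessing signed weighted networks

`splitBySign()` sends positive coefficients to the excitatory network
and magnitudes of negative ones to the inhibitory network — an exact
partition. `pruneNetwork()` then retains the smallest proportion $p$ of
strongest weights such that (i) at least $\lceil 0.99 N \rceil$ vertices
lie in the largest weakly connected component and (ii) every vertex
inside it keeps at least $2 \ln N$ distinct neighbors (undirected
skeleton degree). Reading "connected" as weak-component membership and
"degree" as distinct-neighbor count is a choice — thresholding
toolboxes leave both open — and both bounds are arguments. Vertices
outside the largest component (at most the tolerated 1 %) are exempt
from the degree bound, without which the two criteria could never hold
jointly once any vertex is disconnected. Determinism: weights are ranked
by magnitude with ties broken by (row, column) index, making the
retained arc set monotone in $p$; the minimal $p$ is found by a 0.5 %
grid scan refined by bisection to single-arc granularity, followed by a
downward feasibility walk that guards the (unobserved in practice)
non-monotone corner where a newly joined component member lowers the
minimum degree.

## The synthetic generators as study conditions

`randomDigraph(n, pArc, pRec)` draws each unordered pair independently:
connected with `pArc`, reciprocal with `pRec` given connected, else
uniformly oriented — the minimal model with tunable reciprocity, which
is the structural feature the signature coordinates react to.

`gcaCohort()` emulates the output of ROI-wise signed Granger-causality
analysis at its published scale: 116 regions and 40 subjects by
default, dense lognormal weight magnitudes (`sdLog = 1`, heavy tails so
proportional pruning has real work to do), 60 % positive entries
(excitatory-dominant, as effective brain networks are reported to be),
a cohort-shared base matrix plus per-subject lognormal noise
(`noiseSd = 0.4`) so consensus has genuine signal, and 6 planted
out-hub regions (`hubBoost = 1.5` log-units) for degree heterogeneity.
These defaults were fixed once as the package's study conditions. What
the generator does *not* emulate: autocorrelated BOLD time series and
the estimation noise structure of actual GCA, spatial organization of
regions, sign-coherent blocks (available via constructing the base
matrix yourself), or subject-level covariates. Tests passing on these
cohorts therefore demonstrate that the *procedures* behave as
specified, not that any particular neurobiological conclusion
reproduces; the published cohort-level percentages depend on the
original 40 subjects' fMRI-derived networks, which are not packaged.

Problem sizes used by the suite — $n \le 12$ for the oracle sweep,
$n = 60$ with 2000 replicates for the null convergence, 20-subject
cohorts at 116 regions for planted recovery, and 2 study-scale pruning
runs — were chosen as the smallest sizes at which each statistical
check has comfortable power at its stated tolerance (4 $\sigma$ for
Monte-Carlo checks, binomial 3 $\sigma$ for planted fractions).

## Degenerate inputs and numerical notes

* All counting is integer arithmetic; the only divisions (halving
  ordered-pair and ordered-assignment counts) assert evenness first.
* An empty or edgeless network yields all-zero signatures; block
  normalization maps zero blocks to zero fractions with a `degenerate`
  flag instead of dividing by zero.
* GCM computation refuses fewer than 3 vertices (a correlation from 2
  points is always $\pm 1$ and meaningless here).
* Edge lists serialize reciprocal edges as both ordered records and
  carry the vertex set in a `# vertices:` comment so isolated vertices
  survive round trips.
* `flipDirections`, `randomDigraph` and `gcaCohort` are deterministic
  under their seeds; cohort generation requires a seed outright.

## Known limitations

* Counting is dense $O(n^3)$ via matrix products — right for
  connectome-scale networks ($n \sim 10^2$–$10^3$), wasteful for large
  sparse graphs, where a neighbor-intersection path would win.
* Graphlets stop at 3 nodes; 4-node classes and position-resolved
  (orbit-level) counts within the 3-node classes are out of scope.
* The GCM summarizes linear (Pearson) dependence between count columns;
  monotone-nonlinear alternatives (Spearman) are not offered because
  the downstream thresholds are defined on Pearson coefficients.
* Only the direction-randomization null is provided; degree-preserving
  edge-swap nulls are deliberately absent (the method's point is to be
  null-model-free at the counting stage).
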