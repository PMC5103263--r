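Package: digraphlets
Title: Directed Graphlet Signatures and Correlation Analysis of Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Graphlet-based analysis of simple directed networks with
    reciprocal edges. Computes per-vertex 16-dimensional signature vectors
    from 2-node degrees and 3-node wedge and triangle isomorphism-class
    counts, per-network 16x16 graphlet correlation matrices, and
    cohort-level consensus matrices of significant (anti)correlations.
    Includes a direction-randomization null model that preserves the
    undirected skeleton, sign splitting and density pruning of signed
    weighted connectivity matrices (such as Granger-causality coefficient
    matrices of brain effective networks), a brute-force enumeration
    oracle for small subgraph isomorphism classes, and generators for
    synthetic directed networks and signed weighted cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, igraph, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'DirectedNetwork-io.R'
    'oracle.R'
    'signatures.R'
    'gcm.R'
    'cohort.R'
    'cli.R'
    'digraphlets-package.R'
    'null-models.R'
    'preprocess.R'
    'synthetic.R'
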