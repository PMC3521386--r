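Package: pcoba
Title: Probabilistic Coevolutionary Biclustering of Gene Expression Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers delta-biclusters (submatrices with low mean squared
    residue, high row variance and large volume) in gene expression matrices
    by coevolving a gene-subset population and a condition-subset population
    under population-based incremental learning (PBIL) probability-vector
    updates. Implements the PCOBA coevolutionary engine together with three
    evolutionary baselines (a mutation-only genetic algorithm, a
    coevolutionary genetic algorithm and a single-population estimation of
    distribution algorithm) sharing one residue/variance/volume score,
    planted-bicluster synthetic benchmark generators with ground truth, and
    budget-matched multi-run comparison experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'score.R'
    'matrixio.R'
    'engine.R'
    'baselines.R'
    'synthetic.R'
    'experiments.R'
    'pcoba-package.R'
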