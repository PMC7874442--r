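Package: pangloss
Title: Prokaryotic Pangenome Gene Gain and Loss Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the evolution of prokaryotic pangenomes by stochastic
    gene gain and loss along a phylogeny. Provides exact combinatorial
    transforms between genome intersections and the U-shaped gene
    commonality distribution via the inclusion-exclusion principle, a
    Gillespie simulator of gene content evolution on trees under
    infinite- or finite-gene-pool and constant- or varying-genome-size
    regimes, spanning-subtree distance distributions for genome subsets,
    and multi-class exponential-decay least-squares fitting to infer gene
    turnover rates from presence/absence matrices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    lhs,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
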