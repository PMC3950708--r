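Package: dupcoal
Title: Coalescent Modeling of Gene Duplication and Deletion in Paired
    Tumor-Normal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Models gene duplication and deletion as a two-state
    continuous-time Markov chain evolving along coalescent genealogies.
    Provides exact frequency-class (site-pattern) probabilities by
    resolvent marginalization over coalescent epochs, maximum-likelihood
    estimation of the duplication fraction m and the population parameter
    theta from gene-by-genome presence/absence matrices, chi-square
    goodness-of-fit testing, per-patient estimation of tumor-leading
    branch parameters from paired normal/tumor calls, a binomial test
    identifying tumor-associated duplicated genes, a fixed-tree pruning
    likelihood, and a coalescent simulator for parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
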