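Package: phhmm
Title: Parsimonious Higher-Order Hidden Markov Models for Array-CGH
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments ordered Array-CGH log-ratio profiles into deletion,
    unchanged and amplification states with parsimonious higher-order hidden
    Markov models. Transition processes are tree-structured: a state-context
    tree of height k partitions the set of length-k state histories into
    equivalence classes sharing transition parameters, interpolating between
    a Gaussian mixture model (one class) and a full order-k HMM (one class
    per history). Training is Bayesian Baum-Welch expectation maximization
    with conjugate priors and, in every maximization step, exact selection of
    the optimal state-context tree by dynamic programming over the set
    partition lattice. Includes exact forward-backward inference and
    state-posterior decoding for arbitrary model order, ancestral sampling,
    partial-autocorrelation model diagnostics, ranking-based evaluation
    (TPR at fixed FPR, ROC), synthetic Array-CGH data generators with known
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    optparse,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
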