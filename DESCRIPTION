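Package: booleabayes
Title: Probabilistic Boolean Rule Inference and Attractor Analysis for
    Transcription Factor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers partially-constrained probabilistic Boolean rules for a
    transcription-factor regulatory network from steady-state gene
    expression data, using a Bayes-like weighted average over the leaves of
    each target's regulator binary tree. Expression is binarized to
    ON-probabilities with per-gene two-component Gaussian mixtures. The
    fitted network is simulated under general-asynchronous updates to
    locate pseudo-attractors (semi-stable phenotype states) by bounded
    state-transition-graph search, and in-silico transcription-factor
    perturbations (knockdown or forced activation) are scored by the change
    in random-walk escape time from each attractor, identifying master
    regulators and master destabilizers of each phenotype. Includes a
    synthetic-data generator for multi-attractor Boolean networks observed
    through bimodal Gaussian expression noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    mclust,
    jsonlite,
    withr,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
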