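Package: fibrilHMM
Title: Constrained Profile Hidden Markov Models for Light-Chain Amyloid
    Template Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds segment-constrained profile hidden Markov models from
    antibody light-chain amyloid fibril structures, scores candidate
    light-chain sequences against each structural template with a
    shuffle-normalized log-likelihood ratio calibrated to empirical
    quantiles, decides whether a sequence is reliably modelable by
    homology, and prepares a pruned-backbone side-chain modeling job for
    an external force field. Includes log-space forward, backward,
    Viterbi and Baum-Welch (with inertia) inference, an iterative
    top-fraction retraining schedule, a synthetic fixture generator, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    bio3d,
    Biostrings,
    stats,
    utils,
    tools,
    optparse,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
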