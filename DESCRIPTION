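Package: heterochron
Title: Heterochrony Detection in Developmental Sequences on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of the evolution of developmental event sequences
    (organogenesis timelines) on phylogenies.  Timelines are encoded as
    continuous characters scaled to [0, 1], decile-binned cladistic
    characters, or event-pair characters (earlier/simultaneous/later for
    every pair of events).  The package provides Fitch and Sankoff
    parsimony with per-character lengths and ensemble consistency and
    retention indices, random-addition Wagner building with tree
    bisection-reconnection (TBR) branch swapping, strict and majority-rule
    consensus, and the Templeton (Wilcoxon signed-rank) topology test with
    an exact tie-aware null distribution.  Ancestral states are
    reconstructed by weighted squared-change parsimony, by independent
    contrasts with root 95% confidence intervals, and by a one-rate Mk
    model with marginal probabilities.  Heterochronic events are detected
    by the continuous root-CI criterion and by event-pair cracking with
    the total relative change (TRC) statistic.  Branch lengths can be set
    equal or calibrated from a fossil age table.  A simulator of sequence
    evolution with injected heterochronic shifts supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
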