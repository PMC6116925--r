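Package: rnakit
Title: Simplified-Energy-Model RNA Secondary Structure and RNA-RNA
    Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic-programming algorithms for nested RNA secondary
    structures under a simplified per-base-pair energy model: exact
    counting of the structure space, base-pair maximization (Nussinov)
    with optimal and Wuchty-style suboptimal traceback, partition
    function and base-pair/unpaired probabilities (McCaskill rephrased
    for the base-pair model), maximum-expected-accuracy folding, and
    three RNA-RNA interaction prediction paradigms (hybridization-only,
    concatenation/cofold, accessibility-based).  Every dynamic program
    is verifiable against an exhaustive enumeration oracle shipped with
    the package.  Includes FASTA input, dot-bracket and dot-plot export,
    a seeded fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
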