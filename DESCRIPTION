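Package: loopscape
Title: Repertoire Analysis for Combinatorial Protein Scaffold Libraries
Version: 0.1.0
Authors@R: person("loopscape", "maintainers", email = "loopscape@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing deep-sequenced combinatorial libraries of
    small binding scaffolds before and after binder selection. Encodes
    degenerate-codon sitewise library designs and their exact amino-acid
    distributions, simulates naive and selected populations with planted
    ground truth, processes assembled amplicon reads into classified clones
    and aligned loop sequences, builds cluster-weighted sitewise amino-acid
    frequency matrices, computes Shannon-entropy landscapes and enrichment
    statistics, scores evolvability by leave-one-out cross-validated
    log-odds, fits a constrained linear model of evolved sitewise
    distributions from complementarity, stability and homolog inputs, and
    derives per-site structural exposure scores from solvent accessibility
    and a viewing-orientation search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
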