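Package: fitscape
Title: Combinatorial Fitness Landscapes, Degenerate Codon Libraries and
    Dose-Response Analysis for Directed Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing combinatorial active-site mutagenesis
    experiments: expansion and diversity statistics of IUPAC degenerate
    codon libraries with expected-coverage (library completeness)
    estimates; input/output and summary statistics for combinatorial
    genotype-to-fitness landscapes built on EC50 fold-improvements;
    exhaustive enumeration and accessibility classification of stepwise
    evolutionary trajectories over the subset lattice, including greedy
    most-plausible path reconstruction and mutation-network export to
    GraphML/DOT/CSV; multiplicative-null epistasis predictions with
    propagated errors, sign-epistasis classification and unpaired
    t-tests; four-parameter variable-slope EC50 fitting of
    growth-inhibition dose-response data; and seeded synthetic-data
    generators with known ground truth for landscapes and plate data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
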