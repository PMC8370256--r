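Package: phosphoscreen
Title: Differential Phosphosite Screening for Amino Acid Signaling
    Phosphoproteomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-condition quantitative
    phosphoproteomics screens of amino acid signaling. Reads phosphopeptide
    quantification tables, collapses peptides to residue-level phosphosites,
    classifies sites into regulation frames by fold-change thresholds across
    starvation/restimulation contrasts, summarises residue composition and
    per-protein site multiplicity, discovers over-represented sequence motifs
    around phosphosites with an iterative binomial (motif-x style) algorithm,
    performs hypergeometric over-representation analysis against user-supplied
    annotation sets, ranks interaction-network hubs by degree, and generates
    synthetic five-condition data sets with recorded ground truth for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
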