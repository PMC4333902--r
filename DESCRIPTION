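Package: senRNA
Title: Structural Ensemble Neutrality for Structured RNA Discovery
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@senrna.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@senrna.org>
Description: Computes the mutational neutrality of RNA sequences and
    structure-annotated alignments under three ensemble-aware distance
    metrics (structural ensemble neutrality, normalized base-pair
    distance and a Pearson-correlation metric), tests sequences for
    mutational robustness against inverse-folded, composition-matched
    backgrounds refined by neutral random walks, and classifies
    alignments as structured RNA versus decoy with a support vector
    machine over the standard six alignment features plus neutrality.
    Includes a self-contained, exactly enumerable toy thermodynamic
    engine for validation and an adapter for the ViennaRNA command-line
    suite, together with dinucleotide-preserving decoy generation and
    synthetic structured-alignment fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    e1071,
    pROC,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    Biostrings,
    knitr,
    rmarkdown
SystemRequirements: ViennaRNA suite (RNAfold, RNAsubopt, RNAalifold,
    RNAeval, RNAinverse) for the "vienna" folding engine; optional.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
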