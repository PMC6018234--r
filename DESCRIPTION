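Package: snop
Title: Design and Sequencing Analysis for Stoichiometrically Normalizing
    Oligonucleotide Purification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating stoichiometrically
    normalizing oligonucleotide purification (SNOP) panels. Enumerates
    alternating strong/weak hybridization barcodes, assigns barcodes to
    oligo products by Monte Carlo optimization of reaction free-energy
    uniformity under a nearest-neighbor DNA thermodynamic model, predicts
    capture yield and product stoichiometry with a mass-action competitive
    hybridization solver, simulates correlated oligo synthesis errors and
    the capture/cleavage process down to paired sequencing reads, and
    analyzes overlapped paired-end reads for per-oligo purity, error-class
    histograms, relative concentrations, and Gini/Lorenz inequality
    summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
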