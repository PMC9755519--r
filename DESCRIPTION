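Package: smartchar
Title: Characterization Toolkit for Compact RNA-Guided Nucleases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for the biochemical characterization of compact
    RNA-guided nucleases (Cas9-like and HEARO/IscB-family effectors): PAM/TAM
    discovery from randomized-library cleavage sequencing, cut-site distance and
    staggered-overhang profiling, guide mismatch-tolerance mapping from plasmid
    interference counts, arginine-rich protein feature screening (composition
    deviation, motif grammar, isoelectric point), single-guide RNA scaffold
    construction by duplex trimming and tetraloop fusion, and per-position base
    edit and indel quantification from amplicon sequencing. Includes synthetic
    data generators with known ground truth so that every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
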