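Package: plastome
Title: Comparative Analysis of Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative chloroplast genome analysis: detection of
    the quadripartite architecture (LSC, IRb, SSC, IRa) with per-region GC
    content and inverted-repeat junction reports; microsatellite (SSR)
    scanning under MISA-style thresholds and dispersed long-repeat scanning
    in four orientation classes; gap-aware sliding-window nucleotide
    diversity with hypervariable-region (molecular marker) discovery; and
    Goldman-Yang codon-model branch tests of selection (one-ratio versus
    two-ratio dN/dS with likelihood-ratio tests). Includes seed-deterministic
    simulators for quadripartite plastomes with planted repeats, alignments
    with planted diversity hotspots, and codon alignments evolved under
    branch-specific dN/dS, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
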