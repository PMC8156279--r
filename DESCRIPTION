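Package: panmirnome
Title: Pan-Genome miRNomics Across Lineage Panels
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Homology-based microRNA discovery and pan-genome conservation
    analysis across panels of plant genome assemblies. Implements genome
    scanning for mature miRNA candidates, precursor extraction and hairpin
    secondary-structure screening, family-by-lineage presence/absence
    matrices with four-level conservation grouping, directional pairwise
    conservation statistics, repeat-content classification of precursors,
    complementarity-penalty miRNA target prediction with target-site
    accessibility filtering, greedy identity clustering of target
    transcripts, multiplicity distributions, and conserved co-targeting
    (miRNA team) mining. Ships a fully seeded synthetic lineage-panel
    generator with machine-readable truth tables so the whole pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    BiocGenerics,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
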