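Package: zoopipe
Title: Dual-Marker Zooplankton Metabarcoding Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of dual-marker (COI and 18S V9)
    mesozooplankton metabarcoding data: read demultiplexing and quality
    filtering, similarity-threshold naive-LCA taxonomic assignment with a
    stepwise threshold sweep and phylum-conflict cutoff, MOTU clustering
    with de-novo chimera removal and LULU post-clustering curation,
    depth-weighted combination of two marker matrices, alpha diversity
    (Hill numbers with rarefaction/extrapolation and bootstrap intervals),
    beta diversity (square-root Bray-Curtis, NMDS, Ward clustering with
    multiscale-bootstrap node support, SIMPER), non-indigenous-species
    screening, and morphology-versus-molecular record reconciliation.
    Includes a synthetic-community generator so the whole pipeline is
    testable without sequencer data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
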