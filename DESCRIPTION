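Package: neuropep
Title: Peptidomics of Basal-Metazoan Peptidergic Systems
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end computational pipeline for mass-spectrometry-based
    neuropeptide characterization in early-branching animals: monoisotopic
    peptidoform mass and b/y fragment chemistry with the standard search
    modifications (C-terminal amidation, pyroglutamation, methionine
    oxidation); post-search filtering of peptide-spectrum matches down to
    curated amidated peptide lists; precursor annotation with cleavage-site
    classification (dibasic vs acidic), glycine amide-donor detection and
    logo-ready cleavage-context matrices; all-against-all local-alignment
    similarity networks over precursor sequences with Karlin-Altschul
    e-values and connected-component clustering; peptide-GPCR pair
    prediction from linearized outer products of z-scale descriptors with
    a two-class support vector machine; and single-cell UMI normalization
    with summation-based peptide target-cell mapping. Ships seeded
    synthetic-data generators with ground-truth manifests so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    e1071,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
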