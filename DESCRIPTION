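Package: epicross
Title: Tissue-Weighted Cross-Reactivity Assessment of T-Cell Epitopes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assesses candidate immunotherapeutic T-cell epitopes for
    potential cross-reactivity against naturally expressed human proteins.
    Enumerates all proteome segments within a chosen number of mismatches of
    a query peptide ("natural epitopes"), scores their MHC class I
    presentation likelihood from proteasomal cleavage, TAP transport and
    MHC binding, aggregates tissue-specific protein or transcript abundance
    into per-tissue profiles, and summarises them as a tissue-weighted
    cross-reactivity index with a bootstrap uncertainty estimate. Ships
    seeded synthetic fixture generators (proteomes, expression tables,
    scoring matrices) so the whole pipeline is testable without external
    database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
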