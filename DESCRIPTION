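Package: fragcampaign
Title: Crystallographic Fragment-Screening Campaign Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Campaign management for crystallographic fragment screening with
    acoustic liquid handlers. Provides plate and well addressing for sitting-drop
    crystallization plates (96 wells x 3 subwell drops) and 384/1536-well library
    source plates, SDF fragment-library ingest with SMILES canonicalization and
    greedy MaxMin diversity selection over binary structural fingerprints, a
    validated JSON document store with a five-stage campaign state machine,
    acoustic-dispense transfer-list generation with in-drop dispense offsets and
    DMSO bookkeeping, harvest (fishing) result merging with puck/pin scans,
    campaign funnel statistics (soaked, mounted, diffracting, RSCC-pass,
    verified), and a deterministic synthetic-campaign generator for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
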