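Package: OccuPath
Title: Compatibility of Protein Assembly/Disassembly Pathways with
    Genome-Wide Occupancy Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models genome-wide protein-DNA occupancy data (such as
    ChIP-chip percent occupancies of the general transcription factors at
    yeast promoters) as ordered biochemical assembly/disassembly
    mechanisms. Given a fixed association order, enumerates all
    dissociation pathways, decides which are compatible with observed
    occupancy levels via two interval-logic rules, certifies decisions
    with an exact linear-feasibility oracle over state dwell fractions,
    and validates them with irreversible mass-action kinetics fitted by
    multi-start least squares. Includes the probe-level microarray
    preprocessing chain (background normalization, fold-over-background
    centering on tail-to-tail intergenic probes, 0-100% scaling,
    high/low grouping and group consolidation) and a synthetic probe
    data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    boot,
    deSolve,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
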