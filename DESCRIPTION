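Package: biorecipe
Title: Read, Validate, Simulate, and Convert BioRECIPE Interaction Lists
    and Executable Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for the BioRECIPE tabular knowledge-representation
    format used to curate signaling networks and gene regulatory networks.
    Reads, validates and writes the event-based Interaction List layout
    (one signed, directed interaction per row) and the element-based
    Executable Model layout (one discrete variable per row) from CSV, TSV
    and XLSX spreadsheets; assembles executable models from interaction
    lists and disassembles them back; parses and evaluates the discrete
    update-rule notation (min, max, weighted sum, complement and
    highest-level terms); simulates models under synchronous deterministic
    and random-asynchronous stochastic schemes; enumerates attractors and
    basins of small models; and converts to and from SIF edge lists,
    subject-predicate-object triplet tables and generic node/edge tables.
    Includes deterministic network motifs and seeded random generators so
    every operation is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml,
    zip
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
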