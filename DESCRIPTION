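Package: pgclink
Title: Link Protein Groups Across Mass-Spectrometry Runs with Protein Group Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the protein group code algorithm (PGCA), which links
    protein groups reported in per-run MS/MS protein summaries. Local groups
    from each experimental run are merged into global groups by transitive
    overlap of their accession numbers, and each global group receives a
    stable protein group code (PGC) so quantitative values can be compared
    across runs. Includes readers for ProteinPilot- and Proteome
    Discoverer-style tab-delimited protein summaries, three linking modes
    (whole groups, top-gene refinement, top identifier only), incremental
    dictionary updates, cross-run linkage diagnostics (presence matrices,
    common-code curves, mapping change logs, Dice-coefficient comparisons),
    and a synthetic multi-run summary generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
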