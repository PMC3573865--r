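Package: plexcal
Title: Template Standardisation, Dilution Planning and QC for Multiplex PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating multiplex PCR assays with standardised DNA
    templates. Converts fluorometric concentration measurements of cleaned PCR
    products into absolute double-stranded copy numbers from sequence
    composition and molecular weight, plans low-error stepwise serial dilutions
    with propagated pipetting error, screens multiplex primer panels for
    melting-temperature balance, cross-dimers, amplicon size spacing and
    degraded-DNA length limits (with IUPAC-degeneracy-aware in-silico amplicon
    prediction), applies the stepwise primer-concentration balancing rule, and
    derives per-target limits of detection from replicated sensitivity grids.
    Ships a deterministic fixture generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
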