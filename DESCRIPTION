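Package: pepscan
Title: In Silico Saturation Mutagenesis and Selection of Antimicrobial
    Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the in silico directed evolution of short antimicrobial
    peptides: exhaustive single-residue substitution libraries over a template,
    a from-first-principles physicochemical property engine (fixed-contribution
    and Henderson-Hasselbalch net charge, isoelectric point by bisection, GRAVY
    hydropathy, hydrophilicity, hydrophobic fraction, molecular weight,
    instability and aliphatic indices), ingestion of external predictor score
    tables (antimicrobial, anticancer, toxicity, allergenicity), and a staged
    filter/ranking cascade with per-stage exclusion bookkeeping. A seeded
    synthetic-data generator emulates substitution libraries over low-complexity
    threonine-rich templates and predictor score tables, so the whole selection
    funnel is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
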