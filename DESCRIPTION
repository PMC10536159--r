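Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for pharmacovigilance signal detection on FDA Adverse
    Event Reporting System (FAERS) style quarterly ASCII data. Reads the
    DEMO/DRUG/REAC/OUTC tables, collapses multiple case versions to one
    current report per case, maps MedDRA preferred terms to system organ
    classes through a user-supplied hierarchy table, flags target-drug
    exposure, and computes four disproportionality statistics (reporting
    odds ratio, proportional reporting ratio, BCPNN information component,
    and the empirical-Bayes-geometric-mean-style observed/expected ratio)
    with their interval bounds, threshold rules, and strength bands.
    Includes EBGM-ranked screening at the preferred-term and organ-class
    levels, a reverse drug-by-event screen, Table-1-style descriptive
    summaries, and a seeded synthetic-report generator with injected
    drug-event associations and known ground truth for calibration and
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
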