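Package: faerssignal
Title: Disproportionality Analysis of FAERS Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for the FDA Adverse Event Reporting
    System (FAERS) quarterly data extracts: reads the dollar-delimited DEMO,
    DRUG, REAC, OUTC and INDI ASCII tables, deduplicates versioned case
    reports, builds drug-event 2x2 contingency tables over a reporting
    window, and computes the standard disproportionality statistics --
    proportional reporting ratio (PRR), chi-square with optional Yates
    continuity correction, reporting odds ratio (ROR) with 95% confidence
    interval, and the shrinkage information component (IC) with its IC025
    credibility bound -- together with the usual signal criteria
    (PRR >= 2 & chi2 >= 4 & n >= 3; ROR > 1; IC025 > 0). Includes Table-1
    style demographic summaries of a case series and a synthetic FAERS
    generator with known ground truth (planted drug-event association
    strengths, duplicate case versions) so the whole pipeline is testable
    without downloading FAERS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
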