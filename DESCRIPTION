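Package: bwtmosaic
Title: Predisposition Analysis for Bilateral Wilms Tumor from 11p15.5
    Imprinting, Mosaicism and Germline Variant Triage
Version: 0.1.0
Authors@R:
    person("BWT", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to classify 11p15.5 imprinting status (H19/ICR1 and
    KCNQ1OT1/ICR2) from methylation array beta values, detect low-level
    mosaic gain of methylation in peripheral blood against a control
    cohort, triage candidate germline predisposition variants with a
    rule-based decision procedure, compare the two tumors of a synchronous
    bilateral Wilms tumor pair (shared coding and noncoding somatic
    variants, copy-number profile similarity, 11p breakpoint comparison,
    embryonic-origin classification), and integrate the evidence into a
    per-patient predisposition mode with a mosaicism evidence tier.
    Includes a synthetic multi-tissue cohort generator (blood, adjacent
    kidney, paired tumors) with planted ground truth so the whole pipeline
    is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
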