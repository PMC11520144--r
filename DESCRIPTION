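Package: drgaudit
Title: Rules-Based Audit of ICD Code Omissions and DRG Severity Modifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computable-phenotype auditing of inpatient administrative coding
    from raw structured electronic health record extracts. Nineteen
    rules-based disease algorithms (labs, cultures, flowsheets, medications,
    procedures) flag admissions whose clinical data support a comorbidity
    that is absent from the billed ICD-10 code list; billed DRG codes are
    parsed into severity tiers (Base/CC/MCC/Singlet) so under-modified DRGs
    can be flagged for upgrade; the lost reimbursement implied by the
    relative-weighting-factor delta is valued under a payor-stratified rate
    schedule; and coding-accuracy disparities are summarised with exact
    binomial confidence intervals, standardized mean differences, and
    reference-group tests. A seeded synthetic-cohort generator with a latent
    truth table makes every stage runnable and testable without access to
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    digest,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
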