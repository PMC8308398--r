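Package: diabetyper
Title: OGTT-Based Subtyping, Remission and Reversal Adjudication for Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes insulin-resistance and beta-cell indices from five-point
    oral glucose tolerance test (OGTT) curves (Matsuda index, disposition
    index, hepatic insulin resistance index, muscle insulin sensitivity index,
    HOMA-IR) under explicit unit conventions, classifies individuals into
    eight pathophysiological type 2 diabetes subtypes from calibrated index
    cutoffs, adjudicates per-visit diabetes remission and reversal status from
    HbA1c, fasting glucose and structured glucose-lowering medication records,
    and summarizes longitudinal cohort change. Includes a seeded synthetic
    OGTT cohort generator so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
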