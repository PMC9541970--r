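Package: ipvdetect
Title: Rule-Based Detection of Intimate Partner Violence in Emergency
    Department Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tiered rule-based identification of intimate partner violence
    (IPV) related emergency-department encounters from electronic health
    record data. Classifies encounters by ICD-9/ICD-10 diagnosis codes, by a
    lexicon of 23 situational terms, or by an extended lexicon of 49
    additional mechanism-specific terms matched in free-text clinical notes
    after lowercasing, stop-class removal, light stemming, NegEx-style
    negation scoping and history-of-IPV suppression. Includes a synthetic
    labelled note-corpus generator emulating the text phenomena the rules
    must handle (negated mentions, history mentions, auto-populated screening
    templates, distractors, under-coded ICD fields), chart-review sampling
    utilities, and precision/recall evaluation so the whole pipeline is
    testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
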