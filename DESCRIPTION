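Package: glucoreason
Title: Knowledge-Based Reasoning over Self-Collected Diabetes Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hypothesize-and-test reasoning engine for type 1 diabetes
    self-management diaries. Grades the reliability of self-collected data on
    a 0-50 trust scale, detects noticeable medical events (hyperglycemia,
    hypoglycemia, high blood pressure, short sleep), evaluates a causal
    hypothesis tree to explain each event or flag an information gap, and
    renders hedged textual interpretations and summaries for consultation
    support. Includes medical calculators (estimated HbA1c, insulin
    sensitivity via the 1500/1800 rule, insulin-to-carbohydrate ratio via the
    500/450 rule, insulin on board, carbohydrates on board), a declarative
    editable knowledge base, a seeded synthetic diary generator with
    injectable anomalies, and CSV/JSON diary input/output with a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
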