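Package: ahpneeds
Title: Analytic Hierarchy Process Pipelines for User-Need Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for eliciting and prioritizing user needs with the Analytic
    Hierarchy Process (AHP): decision hierarchies with a built-in
    Parkinson's-disease telehealth needs tree, pairwise questionnaire
    generation, reciprocal judgment matrices on the 1-9 scale, eigenvector and
    geometric-mean priority derivation with consistency screening (lambda_max,
    CI, CR) and revision suggestions, geometric-mean group aggregation with
    local/category/global weight propagation and ranking, a Shannon-entropy
    group-consensus index, subgroup comparison (Spearman rank correlation,
    Welch t-tests, boxplot summaries), weighted evaluation of a candidate
    system against the prioritized needs, and a synthetic expert-panel
    generator with controllable noise and subgroup divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
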