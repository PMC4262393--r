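Package: sevclass
Title: Systematic Disease Severity Classification for Carrier Screening Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive importance tiers of clinical disease
    characteristics from ordinal survey ratings via Ward minimum-variance
    hierarchical clustering, and to classify inherited diseases into
    Profound, Severe, Moderate or Mild severity classes from their untreated
    clinical characteristic profiles using a transparent rule-based decision
    algorithm with penetrance filtering. Includes respondent-level survey
    aggregation, a synthetic survey generator for end-to-end testing,
    concordance evaluation against survey-derived severity groups, and
    bootstrap assessment of tier stability. Ships reference fixtures for a
    15-disease expanded carrier screening pilot survey.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
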