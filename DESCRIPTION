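Package: delivcare
Title: Composite Delivery Care Coverage from Household Survey Microdata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures effective coverage of delivery care from DHS/MICS-style
    household survey microdata. Builds an additive 0-5 composite score over
    four maternal-health interventions (facility delivery type, skilled birth
    attendance, 24+ hour facility stay, postnatal check within 48 hours),
    rescaled to 0-100, with survey-weighted country estimates, stratified
    cluster-bootstrap confidence intervals, inverse-sample-size pooled
    estimates, effective-coverage cascades stratified by facility type and
    obstetric-transition phase, wealth-quintile equity gaps, and the
    cross-country linear association between coverage and the maternal
    mortality ratio. Includes a complex-survey synthetic microdata generator
    so the full pipeline is testable without restricted survey files.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    rlang,
    yaml,
    jsonlite,
    withr,
    sandwich,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
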